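# Anisotropy fitting on a small template: the tissue stiffness ratio is
# monotone in the wall modulus fraction, so planted fractions must be
# recoverable from their own simulated ratios. (Round-trip results are
# memoized in the fixture cache and shared with the acceptance suite.)

test_that("fitting to the isotropic ratio returns the isotropic fraction", {
  tmpl <- fit_fixture_template()
  r1 <- planted_fit_ratio(1)
  fit <- fit_longitudinal_fraction(tmpl, r1, protocol = fit_protocol())
  expect_equal(fit$fraction, 1)
  expect_true(fit$linearized)
})

test_that("planted modulus fractions are recovered within 0.05", {
  for (f_star in c(0.3, 0.5, 0.8)) {
    rt <- fit_roundtrip(f_star)
    expect_lt(abs(rt$fit$fraction - f_star), 0.05)
    # the bisection trace must be monotone: ratio increases with fraction
    tr <- rt$fit$trace[order(rt$fit$trace$fraction), ]
    expect_true(all(diff(tr$ratio) > 0))
  }
})

test_that("unreachable targets are reported, not clamped", {
  tmpl <- fit_fixture_template()
  expect_error(fit_longitudinal_fraction(tmpl, 1e6,
                                         protocol = fit_protocol()),
               "exceeds")
})
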