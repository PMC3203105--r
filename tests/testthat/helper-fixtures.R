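# Shared fixtures, built in code at load time.

# the default synthetic world used across tests
tw <- synth_world(seed = 1)

# Monte Carlo estimate of the PIF for an obese-segment shift, by common
# random numbers; independent of the quadrature implementation.
mc_pif_shift <- function(mu, sd, delta, uptake, r, n = 1e6, seed = 42,
                         ref = 21) {
  withr::with_seed(seed, {
    x <- rnorm(n, mu, sd)
    treat <- runif(n) < uptake
    x_cf <- ifelse(x >= 30 & treat, x - delta, x)
    rr_b <- r^(x - ref)
    rr_c <- r^(x_cf - ref)
    diff <- rr_b - rr_c
    est <- mean(diff) / mean(rr_b)
    se <- stats::sd(diff) / (sqrt(n) * mean(rr_b))
    list(pif = est, se = se)
  })
}

# Monte Carlo estimate of the PIF of moving a normal population to the
# ideal N(21, 1) distribution.
mc_pif_ideal <- function(mu, sd, r, n = 1e6, seed = 42, ref = 21) {
  withr::with_seed(seed, {
    rr_b <- r^(rnorm(n, mu, sd) - ref)
    rr_i <- r^(rnorm(n, 21, 1) - ref)
    eb <- mean(rr_b)
    ei <- mean(rr_i)
    est <- 1 - ei / eb
    se <- sqrt(stats::var(rr_i) / (n * eb^2) +
                 ei^2 * stats::var(rr_b) / (n * eb^4))
    list(pif = est, se = se)
  })
}
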