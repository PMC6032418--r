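# Shared fixtures: the bundled CYP1A2-phenacetin study and the measured
# distance table it should reproduce (distances in Angstroms, as printed
# to two decimals in the source study's table).

reference_distances <- function() {
  rbind(
    data.frame(enzyme = "CYP1A2 WT",
               proton = c("H2,6", "H3,5", "-OCH2-", "-COCH3", "-CH3"),
               r = c(6.76, 6.72, 6.55, 7.85, 6.69),
               r_se = c(0.34, 0.43, 0.87, 0.81, 0.45)),
    data.frame(enzyme = "CYP1A2 L382V",
               proton = c("H2,6", "H3,5", "-OCH2-", "-COCH3", "-CH3"),
               r = c(6.34, 6.39, 5.93, 6.79, 6.13),
               r_se = c(0.31, 0.28, 0.31, 0.71, 0.89)),
    data.frame(enzyme = "CYP1A2 N312L",
               proton = c("H2,6", "H3,5", "-OCH2-", "-COCH3", "-CH3"),
               r = c(8.03, 7.94, 7.84, 8.19, 7.83),
               r_se = c(0.42, 0.43, 0.77, 1.12, 0.52)),
    data.frame(enzyme = "CYP1A2 L382V/N312L",
               proton = c("H2,6", "H3,5", "-OCH2-", "-COCH3", "-CH3"),
               r = c(6.72, 6.87, 5.96, 6.62, 6.92),
               r_se = c(0.31, 0.47, 0.35, 0.15, 0.34)))
}

# closed-form simple linear regression, independent of stats::lm
ols_oracle <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  slope <- sum((x - mx) * (y - my)) / sum((x - mx)^2)
  intercept <- my - slope * mx
  fitted <- intercept + slope * x
  r2 <- 1 - sum((y - fitted)^2) / sum((y - my)^2)
  list(slope = slope, intercept = intercept, r_squared = r2)
}
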