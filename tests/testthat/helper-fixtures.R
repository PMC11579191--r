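# Shared fixtures: the worked parameter sets from the published figure
# captions, and small independent oracles used across test files.

# oral / F.A.T. kinetics (hours, mg, 1/mL)
p_oral <- pk_parameters(ka = 0.42, ke = 0.40, gamma = 0.00449)
# bolus elimination rate
ke_bolus <- 0.3838
# irregular bolus regimen (doses are concentration increments, mg/mL)
reg_bolus_irr <- dose_regimen(doses = c(600, 600, 700, 500, 400, 300),
                              intervals = c(4, 4, 8, 4, 6, 4))
# irregular F.A.T. regimen, 2 h absorption per cycle
reg_fat_irr <- fat_regimen(dose_regimen(c(600, 600, 400, 700),
                                        c(6, 4, 5, 5)), fat = 2)

rel_dev <- function(x, ref) {
  scale <- max(abs(ref))
  if (scale == 0) return(max(abs(x - ref)))
  max(abs(x - ref)) / scale
}

# literal O(n^2) double-sum definition of the dose-history sums,
# independent of the package's forward recursion
literal_history_sum <- function(rate, doses, intervals, n) {
  f <- exp(-rate * intervals)
  total <- doses[n]
  if (n > 1) for (i in 1:(n - 1)) total <- total + doses[i] * prod(f[i:(n - 1)])
  total
}

# superposition of independent mono-exponential decays (bolus oracle)
superposition_bolus <- function(ke, regimen, t) {
  tn <- dose_times(regimen)
  vapply(t, function(tt) {
    past <- which(tn[seq_len(regimen$n)] <= tt)
    sum(regimen$doses[past] * exp(-ke * (tt - tn[past])))
  }, numeric(1))
}
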