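# Shared fixtures built in code. Parameter values follow the study
# conditions the generators default to (FP_LD-like two-transition
# thermograms; EP/FP/OP mass mixture; PBS solvent).

fp_ld_first <- list(Tm_C = 62.0, dH = 1.46e5)
fp_ld_second <- list(Tm_C = 73.7, dH = 3.21e5)

mp_three_components <- function() {
  data.frame(label = c("EP", "FP", "OP"),
             mean = c(3.73e6, 4.51e6, 5.3e6),
             sd = c(0.12e6, 0.12e6, 0.15e6),
             weight = c(0.2, 0.6, 0.2))
}

capsid_vbar <- function() {
  composite_vbar(data.frame(mass_Da = c(3.73e6, 0.8e6),
                            vbar = c(0.730, 0.550)))
}

# brute-force cargo enumeration oracle: nested loops over counts
brute_force_cargo <- function(target, masses, bases, tol, max_bases,
                              max_each = 20) {
  sol <- list()
  nmax <- pmin(floor((target + tol) / masses), max_each)
  grid <- do.call(expand.grid, lapply(nmax, function(m) 0:m))
  for (i in seq_len(nrow(grid))) {
    cnt <- as.numeric(grid[i, ])
    tm <- sum(cnt * masses); tb <- sum(cnt * bases)
    if (abs(tm - target) <= tol && tb <= max_bases)
      sol[[length(sol) + 1L]] <- cnt
  }
  if (!length(sol)) return(matrix(numeric(), 0, length(masses)))
  do.call(rbind, sol)
}
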