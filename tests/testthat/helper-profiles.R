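# Analytic movement profiles used as oracles across the metric tests.

# minimum-jerk smoothstep and its derivatives (per unit time)
mj_s <- function(tau) 10 * tau^3 - 15 * tau^4 + 6 * tau^5
mj_v <- function(tau) 30 * tau^2 - 60 * tau^3 + 30 * tau^4
mj_jerk <- function(tau) 60 - 360 * tau + 360 * tau^2

# 1-D minimum-jerk reach of length L (mm) and duration T (s) along x
min_jerk_positions <- function(L, T, fs) {
  n <- round(T * fs) + 1L
  tau <- seq(0, 1, length.out = n)
  cbind(L * mj_s(tau), 0, 0)
}

min_jerk_speed <- function(L, T, fs) {
  n <- round(T * fs) + 1L
  tau <- seq(0, 1, length.out = n)
  L / T * mj_v(tau)
}

# independent quadrature oracle for the log dimensionless jerk of a pure
# minimum-jerk reach: ln( T^5/L^2 * int ||jerk||^2 dt )
ldlj_min_jerk_oracle <- function(L, T) {
  int_j2 <- stats::integrate(function(tau) (L / T^3 * mj_jerk(tau))^2,
                             0, 1)$value * T
  log(T^5 / L^2 * int_j2)
}

# brute-force confusion counter independent of evaluate_predictions()
brute_confusion <- function(truth, pred) {
  tp <- 0L; fp <- 0L; tn <- 0L; fn <- 0L
  for (i in seq_along(truth)) {
    if (truth[i] && pred[i]) tp <- tp + 1L
    else if (!truth[i] && pred[i]) fp <- fp + 1L
    else if (!truth[i] && !pred[i]) tn <- tn + 1L
    else fn <- fn + 1L
  }
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       sens = tp / (tp + fn), spec = tn / (tn + fp),
       prec = tp / (tp + fp),
       ba = (tp / (tp + fn) + tn / (tn + fp)) / 2)
}
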