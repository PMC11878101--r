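# shared fixtures: a reference model/covariates and small simulated records

ref_pop <- function(...) population_model(...)
ref_cov <- function(...) covariates(...)

# noise-free measurements on the true curve of an individual with known eta
simulated_record <- function(pop, cov, eta, times, method = "TSB",
                             noise_sd = 0, seed = 1) {
  truth <- trajectory(pop, cov, eta, times)
  set.seed(seed)
  vals <- pmax(truth + rnorm(length(times), 0, noise_sd), 0)
  bili_measurements(times, vals, method)
}

# independent re-implementation of the selection rules with different
# primitives (index Filters over the TcB-first chronological ordering);
# returns NULL on rejection
oracle_select <- function(m, spec) {
  m <- m[order(m$pna, m$method != "TcB"), , drop = FALSE]
  idx_all <- seq_len(nrow(m))
  ok_method <- m$method %in% spec$methods
  greedy <- integer(0)
  for (k in seq_len(spec$n_inputs)) {
    cands <- Filter(function(i) {
      if (i %in% greedy || !ok_method[i]) return(FALSE)
      if (k == 1) {
        m$pna[i] >= spec$first_window[1] && m$pna[i] <= spec$first_window[2]
      } else {
        m$pna[i] >= m$pna[greedy[k - 1]] + spec$min_gap &&
          m$pna[i] >= spec$subsequent_window[1] &&
          m$pna[i] <= spec$subsequent_window[2]
      }
    }, idx_all)
    if (!length(cands)) return(NULL)
    greedy <- c(greedy, cands[[1]])
  }
  t_last <- m$pna[greedy[spec$n_inputs]]
  tcands <- unlist(Filter(function(i) {
    !(i %in% greedy) && ok_method[i] &&
      m$pna[i] >= t_last + spec$min_gap &&
      m$pna[i] >= spec$subsequent_window[1] &&
      m$pna[i] <= spec$subsequent_window[2] &&
      m$pna[i] - t_last <= spec$horizon
  }, idx_all))
  if (!length(tcands)) return(NULL)
  tgt <- tcands[which.max(m$pna[tcands])]
  list(input_pna = m$pna[greedy], input_method = m$method[greedy],
       target_pna = m$pna[tgt], target_method = m$method[tgt])
}

# exhaustive enumeration of every (inputs, target) combination satisfying the
# window/gap/method/horizon constraints, ignoring the selection order
enumerate_valid_combos <- function(m, spec) {
  m <- m[order(m$pna, m$method != "TcB"), , drop = FALSE]
  n <- nrow(m)
  if (n < spec$n_inputs + 1) return(list())
  ok_method <- m$method %in% spec$methods
  out <- list()
  for (cmb in utils::combn(n, spec$n_inputs + 1L, simplify = FALSE)) {
    cmb <- cmb[order(m$pna[cmb])]
    ins <- cmb[seq_len(spec$n_inputs)]
    tgt <- cmb[spec$n_inputs + 1L]
    t <- m$pna[ins]
    if (!all(ok_method[cmb])) next
    if (t[1] < spec$first_window[1] || t[1] > spec$first_window[2]) next
    if (spec$n_inputs > 1 &&
        (any(t[-1] < spec$subsequent_window[1]) ||
         any(t[-1] > spec$subsequent_window[2]))) next
    if (any(diff(m$pna[cmb]) < spec$min_gap)) next
    if (m$pna[tgt] < spec$subsequent_window[1] ||
        m$pna[tgt] > spec$subsequent_window[2]) next
    if (m$pna[tgt] - t[length(t)] > spec$horizon) next
    out[[length(out) + 1L]] <- list(input_pna = t, target_pna = m$pna[tgt])
  }
  out
}

random_record <- function(n_meas, seed) {
  set.seed(seed)
  pna <- sort(round(runif(n_meas, 2, 130), 1))
  vals <- runif(n_meas, 50, 300)
  method <- sample(c("TSB", "TcB"), n_meas, replace = TRUE)
  bili_measurements(pna, vals, method)
}
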