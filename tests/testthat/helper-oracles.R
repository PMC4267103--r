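# Independent oracles, deliberately written as literal walks of the stated
# rules rather than closed-form products, so they share no code path with
# the implementation they check.

# all permutations of 1..n (n small)
perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in perms(n - 1)) {
    for (k in seq_len(n)) {
      out[[length(out) + 1]] <- append(p, n, after = k - 1)
    }
  }
  out
}

# brute-force cascade: applies the per-step residual formula sequentially
# under EVERY ordering of the steps; returns the vector of final residuals
oracle_cascade_all_orders <- function(baseline_deaths, steps) {
  vapply(perms(nrow(steps)), function(p) {
    residual <- baseline_deaths
    for (i in p) {
      e <- steps$effectiveness[i]
      residual <- residual * (1 - e * steps$cov_now[i]) /
        (1 - e * steps$cov_base[i])
    }
    residual
  }, numeric(1))
}

# ledger-walk attribution oracle for a single cause: first apply the
# preventive interventions one at a time to the running residual and record
# the block's total deaths averted; split that total in proportion to
# (coverage increase x effectiveness); then apply the curative interventions
# to the preventive residual and split their additional deaths averted the
# same way.
oracle_attribute <- function(baseline_deaths, steps) {
  steps <- steps[steps$effectiveness > 0, ]
  residual <- baseline_deaths
  prev <- steps[steps$category == "preventive", ]
  for (i in seq_len(nrow(prev))) {
    e <- prev$effectiveness[i]
    residual <- residual * (1 - e * prev$cov_now[i]) /
      (1 - e * prev$cov_base[i])
  }
  saved_prev <- baseline_deaths - residual

  residual2 <- residual
  cur <- steps[steps$category == "curative", ]
  for (i in seq_len(nrow(cur))) {
    e <- cur$effectiveness[i]
    residual2 <- residual2 * (1 - e * cur$cov_now[i]) /
      (1 - e * cur$cov_base[i])
  }
  saved_cur <- residual - residual2

  share <- function(block, total) {
    if (nrow(block) == 0) return(NULL)
    w <- (block$cov_now - block$cov_base) * block$effectiveness
    if (sum(w) == 0) {
      return(tibble::tibble(intervention_id = block$intervention_id,
                            lives_saved = 0))
    }
    tibble::tibble(intervention_id = block$intervention_id,
                   lives_saved = total * w / sum(w))
  }
  dplyr::bind_rows(share(prev, saved_prev), share(cur, saved_cur))
}
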