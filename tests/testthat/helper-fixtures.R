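# Shared fixtures: small configurations that keep unit tests fast while the
# acceptance tests use the full default conditions.

small_sim_config <- function(seed = 1L, ...) {
  args <- list(
    grid_dims = c(12L, 14L, 12L),
    n_subjects_per_group = c(30L, 34L),
    n_components = 4L,
    coupled_pair = c(1L, 1L),
    group_effect_components = list(m1 = 2L, m2 = 3L),
    blob_fwhm_mm = 10,
    seed = seed
  )
  do.call(sim_config, modifyList(args, list(...)))
}

quick_pica_config <- function(seed = 1L, ...) {
  args <- list(n_components = 4L, max_iterations = 1500L, seed = seed)
  do.call(pica_config, modifyList(args, list(...)))
}

# Independent flood-fill labelling oracle (recursive BFS, naive) used to
# cross-check the union-find cluster labelling.
floodfill_count <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  keep <- switch(as.character(connectivity),
                 "6" = rowSums(abs(offs)) == 1,
                 "18" = rowSums(abs(offs)) <= 2,
                 "26" = rep(TRUE, nrow(offs)))
  offs <- offs[keep, , drop = FALSE]
  seen <- array(FALSE, d)
  count <- 0L
  for (start in which(mask & !seen)) {
    if (seen[start]) next
    count <- count + 1L
    queue <- start
    seen[start] <- TRUE
    while (length(queue)) {
      cur <- queue[1]
      queue <- queue[-1]
      ijk <- arrayInd(cur, d)
      for (t in seq_len(nrow(offs))) {
        nb <- ijk + offs[t, ]
        if (any(nb < 1) || any(nb > d)) next
        lin <- (nb[3] - 1L) * d[1] * d[2] + (nb[2] - 1L) * d[1] + nb[1]
        if (mask[lin] && !seen[lin]) {
          seen[lin] <- TRUE
          queue <- c(queue, lin)
        }
      }
    }
  }
  count
}

# Exhaustive assignment oracle for small matrices.
brute_force_assignment <- function(cost) {
  n <- nrow(cost)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  best <- NULL
  best_cost <- Inf
  for (p in perms(seq_len(n))) {
    cst <- sum(cost[cbind(seq_len(n), p)])
    if (cst < best_cost) {
      best_cost <- cst
      best <- p
    }
  }
  list(assignment = best, cost = best_cost)
}

# Hand-coded Benjamini-Hochberg step-up oracle (independent of p.adjust).
bh_stepup_oracle <- function(p, alpha) {
  m <- length(p)
  ord <- order(p)
  passed <- which(p[ord] <= alpha * seq_len(m) / m)
  reject <- logical(m)
  if (length(passed)) reject[ord[seq_len(max(passed))]] <- TRUE
  reject
}
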