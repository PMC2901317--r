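# Independent brute-force oracles. These deliberately avoid the code paths of
# the package (base::rank, p.adjust, vectorised formulas) so agreement is a
# genuine cross-check, not a tautology.

# Midranks by counting: rank of x_i = #(x < x_i) + (#(x == x_i) + 1) / 2.
oracle_ranks <- function(m) {
  m <- as.matrix(m)
  r <- m
  for (j in seq_len(ncol(m))) {
    for (i in seq_len(nrow(m))) {
      x <- m[, j]
      r[i, j] <- sum(x < x[i]) + (sum(x == x[i]) + 1) / 2
    }
  }
  r
}

# Selection by explicit enumeration of the tie-break chain.
oracle_select <- function(m, spot_ids) {
  r <- oracle_ranks(m)
  rs <- numeric(nrow(m))
  for (i in seq_len(nrow(m))) rs[i] <- sum(r[i, ])
  best <- which(rs == max(rs))
  if (length(best) > 1) {
    means <- rowMeans(as.matrix(m))[best]
    best <- best[means == max(means)]
  }
  spot_ids[best[1]]
}

# Benjamini-Hochberg from the step-up definition, O(G^2).
oracle_bh <- function(p) {
  g <- length(p)
  ord <- order(p)
  padj_sorted <- numeric(g)
  for (i in seq_len(g)) {
    vals <- numeric(g - i + 1)
    for (j in i:g) vals[j - i + 1] <- min(1, p[ord[j]] * g / j)
    padj_sorted[i] <- min(vals)
  }
  out <- numeric(g)
  out[ord] <- padj_sorted
  out
}

# All permutations of 1..n (plain recursion; n <= 4 in tests).
perms <- function(n) {
  if (n == 1) {
    return(matrix(1L, 1, 1))
  }
  sub <- perms(n - 1)
  out <- matrix(0L, 0, n)
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out <- rbind(out, cbind(k, matrix(rest[sub], nrow(sub), n - 1)))
  }
  unname(out)
}

# Exact permutation null of the Friedman statistic: all (k!)^M assignments of
# within-array rankings, returning the exact upper-tail probability of each
# achievable Q.
friedman_perm_null <- function(k, m) {
  pk <- perms(k)
  idx <- expand.grid(rep(list(seq_len(nrow(pk))), m))
  q <- numeric(nrow(idx))
  for (i in seq_len(nrow(idx))) {
    ranks <- sapply(seq_len(m), function(b) pk[idx[i, b], ])
    rs <- rowSums(ranks)
    q[i] <- 12 / (m * k * (k + 1)) * sum(rs^2) - 3 * m * (k + 1)
  }
  qs <- sort(unique(q))
  tibble::tibble(
    Q = qs,
    p_exact = vapply(qs, function(x) mean(q >= x - 1e-12), 0)
  )
}

# A small probe table built from per-set intensity matrices plus background
# rows, in tidy/tibble form.
make_probe_table <- function(pm_sets, bg) {
  bg <- as.matrix(bg)
  arrays <- paste0("arr", seq_len(ncol(bg)))
  rows <- list()
  for (ps in names(pm_sets)) {
    m <- as.matrix(pm_sets[[ps]])
    tb <- tibble::tibble(
      spot_id = paste0(ps, "_p", seq_len(nrow(m))),
      probeset_id = ps,
      kind = "pm"
    )
    tb[arrays] <- as.data.frame(m)
    rows[[ps]] <- tb
  }
  bgt <- tibble::tibble(
    spot_id = paste0("bg", seq_len(nrow(bg))),
    probeset_id = NA_character_,
    kind = "background"
  )
  bgt[arrays] <- as.data.frame(bg)
  dplyr::bind_rows(c(rows, list(bgt)))
}

# One default-shaped analysis run on simulated data; used by several suites.
run_sim_pipeline <- function(sim, fdr = 0.10) {
  flt <- apply_background_filter(sim$probes, estimate_background(sim$probes))
  fit <- run_maxrs(flt)
  de <- moderated_t_test(
    log2_transform(quantile_normalize(fit)), sim$groups, alpha = fdr
  )
  list(filtered = flt, fit = fit, de = de)
}
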