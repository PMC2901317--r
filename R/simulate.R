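#' Configuration for the synthetic heterologous-hybridization simulator
#'
#' Defaults emulate the regime the method targets: Affymetrix-style probe sets
#' of 11 perfect-match probes, a two-condition design of 4 vs 3 arrays, 10%
#' of genes differentially expressed with linear fold changes spanning 1.6 to
#' 8.4, and a cross-species hybridization model in which exactly one probe
#' per set targets a conserved region (high affinity, Uniform(0.5, 1)) while
#' the rest are sequence-diverged (low affinity, Uniform(0, 0.3)) — so most
#' probes hug the background, and the conserved probe carries the signal.
#'
#' @param n_probesets Number of probe sets T (default 2000).
#' @param probes_per_set Probes per probe set (default 11).
#' @param n_arrays Integer vector `c(M1, M2)` of arrays per condition
#'   (default `c(4, 3)`).
#' @param conditions Two condition labels; the second is the logFC numerator
#'   downstream.
#' @param prop_de Fraction of probe sets with planted differential expression
#'   (default 0.1).
#' @param fc_range Range of planted linear fold changes (default
#'   `c(1.6, 8.4)`).
#' @param baseline_log2_mean,baseline_log2_sd Baseline log2 expression is
#'   Normal(8, 1.5) on the log2 scale.
#' @param affinity_conserved,affinity_diverged Uniform ranges for the
#'   conserved probe's affinity and all other probes' affinities.
#' @param noise_sd Multiplicative noise sd on the natural-log scale
#'   (default 0.25).
#' @param n_background No-probe background spots per array (default 5000).
#' @param background_meanlog,background_sdlog Background intensities are
#'   LogNormal(log 50, 0.4); the same background is also added to every probe
#'   intensity, so the background threshold is meaningful for retention.
#' @param jitter_probes If `TRUE`, probe-set sizes are Poisson(probes_per_set)
#'   truncated at 2 instead of fixed.
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @return A validated list of class `maxrs_sim_config`.
#' @export
sim_config <- function(n_probesets = 2000,
                       probes_per_set = 11,
                       n_arrays = c(4, 3),
                       conditions = c("A", "B"),
                       prop_de = 0.1,
                       fc_range = c(1.6, 8.4),
                       baseline_log2_mean = 8,
                       baseline_log2_sd = 1.5,
                       affinity_conserved = c(0.5, 1),
                       affinity_diverged = c(0, 0.3),
                       noise_sd = 0.25,
                       n_background = 5000,
                       background_meanlog = log(50),
                       background_sdlog = 0.4,
                       jitter_probes = FALSE,
                       seed = 1L) {
  cfg <- list(
    n_probesets = as.integer(n_probesets),
    probes_per_set = as.integer(probes_per_set),
    n_arrays = as.integer(n_arrays),
    conditions = as.character(conditions),
    prop_de = prop_de,
    fc_range = fc_range,
    baseline_log2_mean = baseline_log2_mean,
    baseline_log2_sd = baseline_log2_sd,
    affinity_conserved = affinity_conserved,
    affinity_diverged = affinity_diverged,
    noise_sd = noise_sd,
    n_background = as.integer(n_background),
    background_meanlog = background_meanlog,
    background_sdlog = background_sdlog,
    jitter_probes = isTRUE(jitter_probes),
    seed = as.integer(seed)
  )
  if (cfg$n_probesets < 1 || cfg$probes_per_set < 1) {
    abort_config("need at least one probe set and one probe per set")
  }
  if (length(cfg$n_arrays) != 2 || any(cfg$n_arrays < 2)) {
    abort_config("n_arrays must give two conditions with >= 2 arrays each")
  }
  if (length(cfg$conditions) != 2 ||
    cfg$conditions[1] == cfg$conditions[2]) {
    abort_config("conditions must be two distinct labels")
  }
  if (cfg$prop_de < 0 || cfg$prop_de > 1) {
    abort_config("prop_de must lie in [0, 1]")
  }
  if (length(cfg$fc_range) != 2 || cfg$fc_range[1] < 1 ||
    cfg$fc_range[2] < cfg$fc_range[1]) {
    abort_config("fc_range must be an increasing pair with lower bound >= 1")
  }
  if (cfg$baseline_log2_sd <= 0 || cfg$noise_sd < 0 ||
    cfg$background_sdlog <= 0) {
    abort_config("scale parameters must be positive (noise_sd may be 0)")
  }
  for (rng in list(cfg$affinity_conserved, cfg$affinity_diverged)) {
    if (length(rng) != 2 || rng[1] < 0 || rng[2] > 1 || rng[2] < rng[1]) {
      abort_config("affinity ranges must be increasing pairs within [0, 1]")
    }
  }
  if (cfg$n_background < 1) abort_config("need at least one background spot")
  structure(cfg, class = "maxrs_sim_config")
}

#' Simulate a probe-level heterologous-hybridization experiment
#'
#' Generative model per probe set t: a baseline linear expression
#' `e_t1 = 2^Normal(mu, sd)`; with probability `prop_de` the second condition
#' is shifted to `e_t2 = e_t1 * FC^(+-1)`, FC ~ Uniform(fc_range), direction
#' chosen fairly. Each probe p carries an affinity `a_tp` in `[0, 1]` (one
#' conserved high-affinity probe per set, the rest diverged and low); the
#' intensity of probe p on array m in condition c is
#' `I = a_tp * e_tc * exp(eps) + b`, with `eps ~ Normal(0, noise_sd^2)` and an
#' additive background draw `b ~ LogNormal(background_meanlog,
#' background_sdlog)`. Standalone background spots are drawn i.i.d. from the
#' same log-normal, per array.
#'
#' All randomness flows through R's default Mersenne-Twister stream seeded
#' once from `config$seed`, so an identical seed yields bit-identical output.
#'
#' @param config A [sim_config()].
#' @return An object of class `maxrs_sim`: list with `probes` (probe table,
#'   see [read_probe_table()]), `groups` (array-to-condition tibble),
#'   `truth_genes` (per probe set: linear condition means, `is_de`,
#'   `fold_change`, `direction`, `conserved_spot`), `truth_probes` (per probe:
#'   `affinity`, `is_conserved`) and `config`.
#' @export
simulate_experiment <- function(config = sim_config()) {
  if (!inherits(config, "maxrs_sim_config")) {
    abort_config("`config` must come from sim_config()")
  }
  set.seed(config$seed,
    kind = "Mersenne-Twister", normal.kind = "Inversion",
    sample.kind = "Rejection"
  )
  t_sets <- config$n_probesets
  m_arr <- sum(config$n_arrays)
  cond_of_array <- rep(config$conditions, config$n_arrays)
  array_ids <- unlist(lapply(seq_along(config$conditions), function(i) {
    paste0(config$conditions[i], seq_len(config$n_arrays[i]))
  }), use.names = FALSE)

  # 1. probe-set sizes and conserved-probe positions
  p_t <- if (config$jitter_probes) {
    pmax(2L, rpois(t_sets, config$probes_per_set))
  } else {
    rep(config$probes_per_set, t_sets)
  }
  conserved_pos <- vapply(p_t, function(p) sample.int(p, 1L), 1L)

  # 2. affinities: diverged everywhere, conserved overwritten
  n_probes <- sum(p_t)
  set_of_probe <- rep.int(seq_len(t_sets), p_t)
  within_idx <- sequence(p_t)
  affinity <- runif(
    n_probes, config$affinity_diverged[1], config$affinity_diverged[2]
  )
  is_conserved <- within_idx == conserved_pos[set_of_probe]
  affinity[is_conserved] <- runif(
    t_sets, config$affinity_conserved[1], config$affinity_conserved[2]
  )

  # 3. gene-level truth
  e1 <- 2^rnorm(t_sets, config$baseline_log2_mean, config$baseline_log2_sd)
  is_de <- runif(t_sets) < config$prop_de
  fc <- runif(t_sets, config$fc_range[1], config$fc_range[2])
  direction <- sample(c(-1L, 1L), t_sets, replace = TRUE)
  fc[!is_de] <- 1
  direction[!is_de] <- 0L
  e2 <- e1 * fc^direction

  probeset_ids <- sprintf("ps%05d", seq_len(t_sets))
  spot_ids <- sprintf("%s_p%02d", probeset_ids[set_of_probe], within_idx)

  # 4. probe intensities, one array at a time (fixed draw order)
  e_by_cond <- cbind(e1, e2)
  colnames(e_by_cond) <- config$conditions
  pm_mat <- matrix(0, n_probes, m_arr)
  for (m in seq_len(m_arr)) {
    e_col <- e_by_cond[set_of_probe, cond_of_array[m]]
    noise <- exp(rnorm(n_probes, 0, config$noise_sd))
    bg <- rlnorm(n_probes, config$background_meanlog, config$background_sdlog)
    pm_mat[, m] <- affinity * e_col * noise + bg
  }

  # 5. standalone background spots
  bg_mat <- matrix(0, config$n_background, m_arr)
  for (m in seq_len(m_arr)) {
    bg_mat[, m] <- rlnorm(
      config$n_background, config$background_meanlog, config$background_sdlog
    )
  }

  probes <- tibble::tibble(
    spot_id = c(spot_ids, sprintf("bg%05d", seq_len(config$n_background))),
    probeset_id = c(probeset_ids[set_of_probe],
      rep(NA_character_, config$n_background)),
    kind = rep(c("pm", "background"), c(n_probes, config$n_background))
  )
  probes[array_ids] <- as.data.frame(rbind(pm_mat, bg_mat))

  groups <- tibble::tibble(array_id = array_ids, condition = cond_of_array)
  truth_genes <- tibble::tibble(
    probeset_id = probeset_ids,
    mean_group1 = e1,
    mean_group2 = e2,
    is_de = is_de,
    fold_change = fc,
    direction = direction,
    conserved_spot = sprintf(
      "%s_p%02d", probeset_ids, conserved_pos
    )
  )
  truth_probes <- tibble::tibble(
    spot_id = spot_ids,
    probeset_id = probeset_ids[set_of_probe],
    affinity = affinity,
    is_conserved = is_conserved
  )
  structure(
    list(
      probes = probes, groups = groups,
      truth_genes = truth_genes, truth_probes = truth_probes,
      config = config
    ),
    class = "maxrs_sim"
  )
}

#' @export
print.maxrs_sim <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "Synthetic experiment: %d probe sets (%s probes/set), %d + %d arrays (%s vs %s), %.0f%% DE, seed %d\n",
    cfg$n_probesets,
    if (cfg$jitter_probes) "~" else as.character(cfg$probes_per_set),
    cfg$n_arrays[1], cfg$n_arrays[2],
    cfg$conditions[1], cfg$conditions[2], 100 * cfg$prop_de, cfg$seed
  ))
  invisible(x)
}

truth_genes_of <- function(truth) {
  if (inherits(truth, "maxrs_sim")) truth$truth_genes else truth
}

#' Score probe selection against simulator truth
#'
#' Fraction of probe sets whose MAXRS-selected probe is the planted conserved
#' (maximum-affinity) probe.
#'
#' @param fit A `maxrs_fit` (or its selection tibble).
#' @param truth A `maxrs_sim` or its `truth_genes` tibble.
#' @return One-row tibble: `n_probesets`, `n_correct`, `selection_accuracy`.
#' @export
evaluate_selection <- function(fit, truth) {
  selection <- if (inherits(fit, "maxrs_fit")) fit$selection else fit
  genes <- truth_genes_of(truth)
  j <- dplyr::left_join(
    selection[c("probeset_id", "selected_spot")],
    genes[c("probeset_id", "conserved_spot")],
    by = "probeset_id"
  )
  if (anyNA(j$conserved_spot)) {
    abort_consistency("selection contains probe sets unknown to the truth")
  }
  hit <- j$selected_spot == j$conserved_spot
  tibble::tibble(
    n_probesets = nrow(j),
    n_correct = sum(hit),
    selection_accuracy = mean(hit)
  )
}

#' Score differential-expression calls against simulator truth
#'
#' Sensitivity is true-and-called over all planted DE genes; the observed
#' false discovery rate is called-and-not-true over all calls (0 when nothing
#' is called); direction agreement is the fraction of true-positive calls
#' whose log fold-change sign matches the planted direction.
#'
#' @param de A `maxrs_de` table with `de_call` computed.
#' @param truth A `maxrs_sim` or its `truth_genes` tibble. Condition order in
#'   the truth must match the group file used for testing (it does for tables
#'   from the same simulation).
#' @return One-row tibble: `n_true`, `n_called`, `n_true_positive`,
#'   `sensitivity`, `observed_fdr`, `direction_agreement`.
#' @export
evaluate_de <- function(de, truth) {
  genes <- truth_genes_of(truth)
  j <- dplyr::left_join(
    tibble::as_tibble(unclass(de)[c("probeset_id", "logfc", "de_call")]),
    genes[c("probeset_id", "is_de", "direction")],
    by = "probeset_id"
  )
  if (anyNA(j$is_de)) {
    abort_consistency("DE table contains probe sets unknown to the truth")
  }
  called <- j$de_call != "none"
  tp <- called & j$is_de
  n_true <- sum(genes$is_de)
  tibble::tibble(
    n_true = n_true,
    n_called = sum(called),
    n_true_positive = sum(tp),
    sensitivity = if (n_true > 0) sum(tp) / n_true else NA_real_,
    observed_fdr = if (any(called)) sum(called & !j$is_de) / sum(called) else 0,
    direction_agreement = if (any(tp)) {
      mean(sign(j$logfc[tp]) == j$direction[tp])
    } else {
      NA_real_
    }
  )
}
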