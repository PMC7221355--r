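#' Specification of a synthetic two-group cohort
#'
#' Parameters of the factor-model generator that stands in for a two-group
#' rsfMRI cohort: two diagnostic groups, nodes partitioned into communities,
#' community-structured positive-definite correlation matrices obtained by
#' sampling latent community factors, and Table-1-style covariates (sex
#' imbalance, an age gap, a small head-motion gap). Each node's signal is
#'
#'   x = within_load * (community factor) + b * (global factor) + noise,
#'
#' with unit-variance factors and noise, where b = `between_load` for
#' controls and `between_load + effect_between` for cases on the nodes of
#' `target_networks` (all nodes when `NULL`). Raising b increases
#' between-community correlations, which merges components at lower
#' filtration values and lowers the Betti-0 curve area — the implanted
#' "decreased segregation" of the case group. A factor model always
#' implies a valid (positive semi-definite) population correlation matrix.
#'
#' `effect_between` acts on the global factor, so it touches every
#' internetwork pair involving the target nodes; an effect meant to stay
#' anatomically confined to one community should instead use
#' `effect_within`, which raises the case group's community-factor loading
#' on the target networks and therefore only their intra-community edges.
#'
#' Defaults mirror the structure of a two-site pediatric case-control
#' sample: 81 cases vs 96 controls, 105 nodes in 7 communities, 172 retained
#' time points, a sex odds ratio near 3, an age gap of 1.76 years and a
#' motion gap of 0.005 mm between groups. `effect_between = 0.03` implants
#' a whole-brain AUC shift of about -0.5 SD at these settings.
#'
#' @param n_case,n_control Subjects per group.
#' @param n_nodes Number of nodes.
#' @param k Number of communities.
#' @param t_samples Time points per subject.
#' @param within_load Within-community factor loading in \[0, 1).
#' @param between_load Baseline global-factor loading.
#' @param effect_between Additive global-factor loading for cases on the
#'   target nodes.
#' @param effect_within Additive community-factor loading for cases on
#'   the target networks (default 0).
#' @param target_networks Community labels carrying the effect (`NULL` =
#'   all).
#' @param sex_p_female Probability of female, named `control`/`case`.
#' @param age_mean,age_sd,motion_mean,motion_sd Per-group covariate
#'   parameters, named `control`/`case`.
#' @param seed Master seed; all randomness derives from it.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_case = 81, n_control = 96, n_nodes = 105, k = 7,
                        t_samples = 172, within_load = 0.6,
                        between_load = 0.2, effect_between = 0.03,
                        effect_within = 0, target_networks = NULL,
                        sex_p_female = c(control = 51 / 96, case = 22 / 81),
                        age_mean = c(control = 12.26, case = 10.5),
                        age_sd = c(control = 3.07, case = 2.48),
                        motion_mean = c(control = 0.067, case = 0.072),
                        motion_sd = c(control = 0.054, case = 0.041),
                        seed = 1L) {
  spec <- structure(list(
    n_case = as.integer(n_case), n_control = as.integer(n_control),
    n_nodes = as.integer(n_nodes), k = as.integer(k),
    t_samples = as.integer(t_samples),
    within_load = within_load, between_load = between_load,
    effect_between = effect_between, effect_within = effect_within,
    target_networks = target_networks,
    sex_p_female = sex_p_female, age_mean = age_mean, age_sd = age_sd,
    motion_mean = motion_mean, motion_sd = motion_sd,
    seed = as.integer(seed)), class = "cohort_spec")
  validate_cohort_spec(spec)
  spec
}

validate_cohort_spec <- function(spec) {
  if (spec$n_case < 2 || spec$n_control < 2) {
    stop("need at least 2 subjects per group")
  }
  if (spec$k < 1) stop("k must be at least 1")
  if (spec$n_nodes < spec$k) stop("need at least one node per community")
  if (spec$t_samples < 3) stop("t_samples must be at least 3")
  if (spec$within_load < 0 || spec$within_load >= 1) {
    stop("invalid within_load ", spec$within_load, ": must lie in [0, 1)")
  }
  if (spec$between_load < 0) {
    stop("invalid between_load ", spec$between_load,
         ": must be non-negative")
  }
  if (spec$effect_between < 0 || spec$effect_within < 0) {
    stop("invalid loadings: effect_between ", spec$effect_between,
         " and effect_within ", spec$effect_within,
         " must be non-negative")
  }
  if (spec$between_load + spec$effect_between >= 1) {
    stop("invalid loadings: between_load + effect_between = ",
         spec$between_load + spec$effect_between, " must stay below 1")
  }
  if (spec$within_load + spec$effect_within >= 1) {
    stop("invalid loadings: within_load + effect_within = ",
         spec$within_load + spec$effect_within, " must stay below 1")
  }
  ev <- min(eigen(population_connectome(spec, "case"),
                  symmetric = TRUE, only.values = TRUE)$values)
  if (ev < -1e-8) {
    stop("loadings within_load = ", spec$within_load, ", between_load = ",
         spec$between_load, ", effect_between = ", spec$effect_between,
         " imply a non-positive-semi-definite population matrix")
  }
  if (spec$t_samples < spec$n_nodes / 3) {
    warning("t_samples < n_nodes / 3: sample correlations will be noisy")
  }
  invisible(spec)
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Synthetic cohort spec:", x$n_case, "cases +", x$n_control,
      "controls;", x$n_nodes, "nodes in", x$k, "communities;",
      x$t_samples, "time points\n")
  cat(sprintf("  loadings: within %.2f, between %.2f, case effect +%.2f (%s)\n",
              x$within_load, x$between_load, x$effect_between,
              if (is.null(x$target_networks)) "global"
              else paste(x$target_networks, collapse = ", ")))
  invisible(x)
}

community_labels <- function(spec) {
  sizes <- rep(spec$n_nodes %/% spec$k, spec$k)
  extra <- spec$n_nodes %% spec$k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  rep(paste0("C", seq_len(spec$k)), sizes)
}

node_loadings <- function(spec, is_case) {
  comm <- community_labels(spec)
  b <- rep(spec$between_load, spec$n_nodes)
  w <- rep(spec$within_load, spec$n_nodes)
  if (is_case) {
    hit <- if (is.null(spec$target_networks)) rep(TRUE, spec$n_nodes)
           else comm %in% spec$target_networks
    b[hit] <- b[hit] + spec$effect_between
    w[hit] <- w[hit] + spec$effect_within
  }
  list(comm = comm, within = w, between = b)
}

#' Population correlation matrix implied by a cohort spec
#'
#' The exact correlation matrix of the generating factor model for one
#' group; sample connectomes converge to it as `t_samples` grows.
#'
#' @param spec A [cohort_spec].
#' @param group `"control"` or `"case"`.
#' @return A [connectivity_matrix].
#' @export
population_connectome <- function(spec, group = c("control", "case")) {
  group <- match.arg(group)
  ld <- node_loadings(spec, is_case = group == "case")
  n <- spec$n_nodes
  same <- outer(ld$comm, ld$comm, "==")
  cov_mat <- outer(ld$between, ld$between) +
    same * outer(ld$within, ld$within)
  v <- ld$within^2 + ld$between^2 + 1
  r <- cov_mat / sqrt(outer(v, v))
  diag(r) <- 1
  connectivity_matrix(r, node_ids = sprintf("N%03d", seq_len(n)))
}

simulate_subject <- function(spec, is_case, sub_seed) {
  ld <- node_loadings(spec, is_case)
  t <- spec$t_samples
  with_seed(sub_seed, {
    fac <- matrix(rnorm(t * spec$k), t, spec$k,
                  dimnames = list(NULL, unique(ld$comm)))
    g <- rnorm(t)
    noise <- matrix(rnorm(t * spec$n_nodes), t, spec$n_nodes)
    ts <- fac[, ld$comm, drop = FALSE] * rep(ld$within, each = t) +
      outer(g, ld$between) + noise
    colnames(ts) <- sprintf("N%03d", seq_len(spec$n_nodes))
    ts
  })
}

#' Simulate a synthetic two-group cohort
#'
#' Draws every subject's node signals from the factor model of a
#' [cohort_spec], computes the Pearson connectome, and draws the per-group
#' covariates. Subject i uses sub-seed `derive_seed(seed, i)` and covariates
#' use `derive_seed(seed, 0)`, so the cohort is bit-reproducible and
#' subjects can be generated independently in any order.
#'
#' @param spec A [cohort_spec].
#' @param return_timeseries Also return each subject's time-by-node signal
#'   matrix (needed to re-parcellate the same cohort at another
#'   granularity).
#' @return A list with `connectomes` (named list of
#'   [connectivity_matrix]), `phenotypes` (data frame: subject_id, group,
#'   sex, age, motion), `partition` (a [node_partition] of nodes into
#'   communities), `spec`, and optionally `timeseries`.
#' @export
simulate_cohort <- function(spec, return_timeseries = FALSE) {
  validate_cohort_spec(spec)
  n_total <- spec$n_control + spec$n_case
  group <- factor(rep(c("control", "case"), c(spec$n_control, spec$n_case)),
                  levels = c("control", "case"))
  ids <- sprintf("sub%03d", seq_len(n_total))

  phen <- with_seed(derive_seed(spec$seed, 0), {
    gch <- as.character(group)
    sex <- ifelse(runif(n_total) < spec$sex_p_female[gch], "F", "M")
    age <- rnorm(n_total, spec$age_mean[gch], spec$age_sd[gch])
    motion <- pmax(rnorm(n_total, spec$motion_mean[gch],
                         spec$motion_sd[gch]), 0.001)
    data.frame(subject_id = ids, group = group,
               sex = factor(sex, levels = c("F", "M")),
               age = pmax(age, 4), motion = motion,
               stringsAsFactors = FALSE)
  })

  tslist <- lapply(seq_len(n_total), function(i) {
    simulate_subject(spec, is_case = group[i] == "case",
                     sub_seed = derive_seed(spec$seed, i))
  })
  names(tslist) <- ids
  cms <- lapply(tslist, pearson_connectome)

  part <- node_partition(community_labels(spec),
                         node_ids = sprintf("N%03d", seq_len(spec$n_nodes)))
  out <- list(connectomes = cms, phenotypes = phen, partition = part,
              spec = spec)
  if (return_timeseries) out$timeseries <- tslist
  out
}

#' Refine a partition into finer sub-communities
#'
#' Splits each community's nodes into `split_factor` sub-labels by seeded
#' random assignment, emulating a finer parcellation of the same underlying
#' sources (node count unchanged). Used to test cross-parcellation
#' concordance without real atlases.
#'
#' @param p A [node_partition].
#' @param split_factor Integer >= 1; 1 returns the partition unchanged.
#' @param seed Seed for the assignment.
#' @return A refined [node_partition] with labels `"<label>.<i>"`.
#' @export
refine_partition <- function(p, split_factor, seed = 1L) {
  if (!inherits(p, "node_partition")) p <- node_partition(p)
  split_factor <- as.integer(split_factor)
  if (split_factor < 1) stop("split_factor must be at least 1")
  if (split_factor == 1) return(p)
  labs <- unclass(p)
  new_labs <- labs
  with_seed(seed, {
    for (lab in sort(unique(labs))) {
      ix <- which(labs == lab)
      sub <- sample(rep_len(seq_len(split_factor), length(ix)))
      new_labs[ix] <- paste0(lab, ".", sub)
    }
  })
  node_partition(new_labs, node_ids = names(p))
}
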