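#' @title Synthetic connectome cohort generator
#'
#' @description Generates cohorts of streamline-count connectomes with the
#'   statistical structure the comparison pipeline assumes, so every
#'   downstream stage can be exercised and validated without patient
#'   data. The model is hierarchical, mirroring how tractography count
#'   matrices behave across subjects: a study-level *anatomical backbone*
#'   — nodes on a sphere-like cortical shell, edges present with
#'   probability decaying exponentially in inter-centroid distance, and a
#'   heavy-tailed (lognormal) base weight per edge — is shared by every
#'   subject of a study, while subjects vary through multiplicative
#'   per-edge noise and a global scale factor (tractography seeds the
#'   same total streamline budget in everyone, so between-subject scale
#'   variation is modest). Cognitive impairment is planted as
#'   multiplicative attenuation of all edges incident to a set of target
#'   nodes — graded loss of connectivity rather than outright deletion —
#'   driven by a per-subject latent severity, and the CI index is coupled
#'   to the same severity so that the correlation stage has a recoverable
#'   signal.
#' @name synthetic-data
NULL

GORDON_COMMUNITIES <- c("ventral attention", "cingulo-opercular",
                        "default mode", "visual", "somato-motor",
                        "temporal")

#' Generator configuration
#'
#' Defaults mirror the study conditions the pipeline is meant for: a
#' 333-node parcellation and cohorts of 10 non-impaired vs 31 impaired
#' subjects.
#'
#' @param n_nodes parcellation size (default 333).
#' @param n_msni,n_msci cohort sizes (defaults 10 and 31).
#' @param decay_length edge-probability decay length in mm (default 45):
#'   `P(edge ij) = exp(-dist_ij / decay_length)` in the shared backbone.
#' @param weight_meanlog,weight_sdlog lognormal base streamline-count
#'   model across backbone edges (defaults 3 and 1: median ~20
#'   streamlines, heavy upper tail).
#' @param planted_nodes nodes whose incident edges are attenuated in
#'   impaired subjects (default `c(5, 17)`).
#' @param effect_delta attenuation strength in `[0, 1)` (default 0.5):
#'   incident edge weights are multiplied by `1 - effect_delta * severity`.
#' @param edge_noise_sigma sdlog of the per-subject, per-edge lognormal
#'   noise around the backbone base weight (default 0.35, in the range of
#'   reported scan-rescan variability of streamline counts).
#' @param subject_noise_sigma sdlog of the per-subject global scale factor
#'   (default 0.1).
#' @param ci_coupling slope tying the CI index logit to the latent
#'   severity (default 2).
#' @param ci_noise_sigma sd of the CI index logit noise (default 0.2);
#'   widening it produces borderline subjects for exclusion-path testing.
#' @param seed root seed; all subject-level randomness is fanned out from
#'   it deterministically.
#' @return list of class `generator_config`.
#' @export
generator_config <- function(n_nodes = 333, n_msni = 10, n_msci = 31,
                             decay_length = 45, weight_meanlog = 3,
                             weight_sdlog = 1, planted_nodes = c(5, 17),
                             effect_delta = 0.5, edge_noise_sigma = 0.35,
                             subject_noise_sigma = 0.1,
                             ci_coupling = 2, ci_noise_sigma = 0.2,
                             seed = 1) {
  stopifnot(n_nodes >= 2, n_msni >= 2, n_msci >= 2,
            effect_delta >= 0, effect_delta < 1, decay_length > 0,
            all(planted_nodes >= 1), all(planted_nodes <= n_nodes))
  structure(list(n_nodes = as.integer(n_nodes),
                 n_msni = as.integer(n_msni), n_msci = as.integer(n_msci),
                 decay_length = decay_length,
                 weight_meanlog = weight_meanlog,
                 weight_sdlog = weight_sdlog,
                 planted_nodes = as.integer(planted_nodes),
                 effect_delta = effect_delta,
                 edge_noise_sigma = edge_noise_sigma,
                 subject_noise_sigma = subject_noise_sigma,
                 ci_coupling = ci_coupling,
                 ci_noise_sigma = ci_noise_sigma,
                 seed = as.integer(seed)),
            class = "generator_config")
}

# Deterministic per-subject / per-stage seed fan-out from the root seed
# (Lehmer-style mix, kept below 2^31 - 1).
fan_out_seed <- function(root, k) {
  as.integer((as.double(root) * 48271 + 7919 * as.double(k)) %% 2147483647)
}

#' Generate a synthetic parcellation
#'
#' Centroids are placed on a cortical-shell-like sphere (radius ~70 mm
#' with radial jitter), hemispheres assigned by the sign of x, and
#' functional communities assigned round-robin from the standard
#' community names.
#'
#' @param n_nodes number of nodes (>= 2).
#' @param seed integer seed.
#' @return a [parcellation()].
#' @export
generate_parcellation <- function(n_nodes = 333, seed = 1) {
  stopifnot(n_nodes >= 2)
  set.seed(seed)
  dirs <- matrix(rnorm(3 * n_nodes), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  radius <- 70 * (1 + runif(n_nodes, -0.1, 0.1))
  xyz <- dirs * radius
  hemi <- ifelse(xyz[, 1] < 0, "L", "R")
  community <- rep(GORDON_COMMUNITIES, length.out = n_nodes)
  parcellation(data.frame(
    node_id = seq_len(n_nodes),
    label = sprintf("%s_%s_%03d", hemi,
                    gsub("[^a-z]", "", community), seq_len(n_nodes)),
    community = community, hemisphere = hemi,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    stringsAsFactors = FALSE))
}

# Study-level anatomical backbone shared by every subject: the edge set
# (distance-decay existence, drawn once from the config seed) and a
# heavy-tailed base weight per edge, plus the mask of edges incident to a
# planted node. Deterministic in (parc, cfg).
study_backbone <- function(parc, cfg) {
  xyz <- as.matrix(parc[, c("x", "y", "z")])
  N <- nrow(xyz)
  ut <- which(upper.tri(matrix(0, N, N)), arr.ind = TRUE)
  i <- ut[, 1]
  j <- ut[, 2]
  d <- sqrt(rowSums((xyz[i, , drop = FALSE] - xyz[j, , drop = FALSE])^2))
  p_edge <- exp(-d / cfg$decay_length)
  set.seed(fan_out_seed(cfg$seed, 999983L))
  exist <- runif(length(p_edge)) < p_edge
  base <- rlnorm(length(p_edge), cfg$weight_meanlog, cfg$weight_sdlog)
  i <- i[exist]
  j <- j[exist]
  list(N = N, i = i, j = j, base = base[exist],
       planted_edge = (i %in% cfg$planted_nodes) |
                      (j %in% cfg$planted_nodes))
}

# Draw backbone-edge weight columns for length(severities) subjects under
# the current RNG state: base weight x per-edge lognormal noise x
# per-subject scale, attenuated at planted edges (severity 0 = control),
# rounded to integer streamline counts. n_edges x n_subjects matrix.
sample_weight_columns <- function(bb, cfg, severities) {
  n_edges <- length(bb$base)
  n_subj <- length(severities)
  factors <- rlnorm(n_subj, 0, cfg$subject_noise_sigma)
  W <- matrix(rlnorm(n_edges * n_subj, 0, cfg$edge_noise_sigma),
              nrow = n_edges)
  W <- W * bb$base
  W <- W * rep(factors, each = n_edges)
  atten <- 1 - cfg$effect_delta * severities
  if (any(bb$planted_edge) && any(atten < 1)) {
    W[bb$planted_edge, ] <- W[bb$planted_edge, ] *
      rep(atten, each = sum(bb$planted_edge))
  }
  round(W)
}

# Latent severity of an impaired subject: bounded away from 0 so that
# every impaired subject carries a detectable deficit, with spread for the
# correlation stage. Support [0.5, 1], mean 0.75.
draw_severity <- function(n = 1) 0.5 + 0.5 * rbeta(n, 2, 2)

#' Generate one subject's connectome
#'
#' Deterministic in `(parc, config, group, subject_seed)`: the anatomical
#' backbone is derived from the config seed (shared by all subjects of a
#' study) and the subject's own noise from `subject_seed`. For
#' `group = "impaired"` a latent severity is drawn first and every edge
#' incident to a planted node is attenuated by
#' `1 - effect_delta * severity`; weights are then rounded to integer
#' streamline counts (attenuated edges can round to 0 and disappear,
#' modelling graded structural loss).
#'
#' @param parc a [parcellation()].
#' @param config a [generator_config()].
#' @param group `"control"` or `"impaired"`.
#' @param subject_seed integer seed for this subject.
#' @return a [connectome()] with attributes `severity` and
#'   `latent_group`.
#' @export
generate_subject_connectome <- function(parc, config,
                                        group = c("control", "impaired"),
                                        subject_seed = 1) {
  group <- match.arg(group)
  stopifnot(inherits(config, "generator_config"))
  bb <- study_backbone(parc, config)
  set.seed(subject_seed)
  severity <- if (group == "impaired") draw_severity(1) else 0
  w <- sample_weight_columns(bb, config, severity)[, 1]
  if (sum(w) == 0)
    stop("degenerate generator: no edges survived", call. = FALSE)
  W <- matrix(0, bb$N, bb$N)
  W[cbind(bb$i, bb$j)] <- w
  W[cbind(bb$j, bb$i)] <- w
  cn <- connectome(W, parc)
  attr(cn, "severity") <- severity
  attr(cn, "latent_group") <- group
  cn
}

# CI index of one subject from its latent severity: logistic link anchored
# at typical-control level for severity 0 and above the MSCI threshold for
# the attenuated group at default coupling.
draw_ci_index <- function(severity, cfg, thresholds = ci_thresholds()) {
  base <- if (severity > 0) qlogis(thresholds$msci_min) else qlogis(0.10)
  plogis(base + cfg$ci_coupling * severity +
           rnorm(length(severity), 0, cfg$ci_noise_sigma))
}

#' Generate a full synthetic two-cohort study
#'
#' Draws `n_msni` control-like and `n_msci` impaired subjects, each with a
#' connectome and a CI index coupled to the same latent severity that
#' drives the connectivity deficit. Group labels are assigned from the CI
#' index via [classify_ci()] — not from the latent assignment — so
#' borderline indices (possible under widened `ci_noise_sigma`) are
#' labelled and excluded exactly as they would be in a real study.
#'
#' @param config a [generator_config()].
#' @param thresholds [ci_thresholds()] used for labelling.
#' @return a [cohort_dataset()]; each subject record carries `severity`
#'   and `latent_group` attributes.
#' @export
generate_cohort_study <- function(config = generator_config(),
                                  thresholds = ci_thresholds()) {
  stopifnot(inherits(config, "generator_config"))
  parc <- generate_parcellation(config$n_nodes,
                                seed = fan_out_seed(config$seed, 0))
  n_total <- config$n_msni + config$n_msci
  subjects <- vector("list", n_total)
  for (k in seq_len(n_total)) {
    latent <- if (k <= config$n_msni) "control" else "impaired"
    sseed <- fan_out_seed(config$seed, k)
    cn <- generate_subject_connectome(parc, config, latent, sseed)
    severity <- attr(cn, "severity")
    ci <- draw_ci_index(severity, config, thresholds)
    rec <- subject_record(sprintf("sub-%03d", k),
                          group = classify_ci(ci, thresholds),
                          ci_index = ci, connectome = cn)
    attr(rec, "severity") <- severity
    attr(rec, "latent_group") <- latent
    subjects[[k]] <- rec
  }
  cohort_dataset(parc, subjects)
}

#' Write a complete synthetic study to disk
#'
#' Produces, under `dir`, the three inputs the readers consume: a node
#' table (`nodes.tsv`), one connectivity matrix per subject
#' (`matrices/<subject_id>.tsv`) and a manifest (`manifest.tsv` with
#' `subject_id`, `group`, `ci_index`, `matrix_path`).
#'
#' @param config a [generator_config()].
#' @param dir output directory (created if needed).
#' @return `invisible(dir)`.
#' @export
simulate_study_files <- function(config = generator_config(), dir) {
  dataset <- generate_cohort_study(config)
  dir.create(file.path(dir, "matrices"), recursive = TRUE,
             showWarnings = FALSE)
  write_node_table(dataset$parcellation, file.path(dir, "nodes.tsv"))
  man <- data.frame(subject_id = character(0), group = character(0),
                    ci_index = numeric(0), matrix_path = character(0))
  for (s in dataset$subjects) {
    rel <- file.path("matrices", paste0(s$subject_id, ".tsv"))
    write_connectivity_matrix(s$connectome, file.path(dir, rel))
    man <- rbind(man, data.frame(subject_id = s$subject_id,
                                 group = s$group, ci_index = s$ci_index,
                                 matrix_path = rel))
  }
  write.table(man, file.path(dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Empirical family-wise error rate under a complete null
#'
#' Simulates replicate null studies — all subjects drawn from the same
#' generator distribution with no planted effect — computes per-subject
#' node strengths, splits the subjects into cohorts of `n_msni` and
#' `n_msci`, runs the nodewise pooled-t / Holm-Sidak comparison, and
#' records whether any node was (falsely) rejected. The fraction of
#' replicates with at least one rejection estimates the family-wise error
#' rate of the comparison stage.
#'
#' @param n_replicates number of null studies.
#' @param config a [generator_config()]; its `effect_delta` is ignored
#'   (subjects are generated as controls).
#' @param alpha level of the Holm-Sidak procedure (default 0.05).
#' @param seed root seed for the whole simulation.
#' @return list with `fwer` (scalar), `any_rejection` (logical per
#'   replicate), `n_rejections` (integer per replicate), `n_replicates`,
#'   `mc_se` (binomial Monte-Carlo standard error of `fwer`).
#' @export
fwer_null_simulation <- function(n_replicates, config = generator_config(),
                                 alpha = 0.05, seed = 1) {
  stopifnot(n_replicates >= 1)
  parc <- generate_parcellation(config$n_nodes,
                                seed = fan_out_seed(seed, 0))
  n_subj <- config$n_msni + config$n_msci
  any_rej <- logical(n_replicates)
  n_rej <- integer(n_replicates)
  for (r in seq_len(n_replicates)) {
    cfg_r <- config
    cfg_r$seed <- fan_out_seed(seed, 2L * r)  # fresh backbone per study
    bb <- study_backbone(parc, cfg_r)
    set.seed(fan_out_seed(seed, 2L * r + 1L))
    W <- sample_weight_columns(bb, cfg_r, rep(0, n_subj))
    S <- matrix(0, config$n_nodes, n_subj)  # node strengths
    acc <- rowsum(rbind(W, W), c(bb$i, bb$j))
    S[as.integer(rownames(acc)), ] <- acc
    S <- t(S)
    msni <- S[seq_len(config$n_msni), , drop = FALSE]
    msci <- S[config$n_msni + seq_len(config$n_msci), , drop = FALSE]
    tab <- nodewise_comparison(msci, msni, alpha = alpha,
                               measure_name = "strength")
    n_rej[r] <- sum(tab$reject, na.rm = TRUE)
    any_rej[r] <- n_rej[r] > 0L
  }
  fwer <- mean(any_rej)
  list(fwer = fwer, any_rejection = any_rej, n_rejections = n_rej,
       n_replicates = n_replicates,
       mc_se = sqrt(fwer * (1 - fwer) / n_replicates))
}
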