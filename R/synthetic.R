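# Synthetic cohort generator.  No public dataset of parkinsonian
# radiomic feature tables exists, so validation runs on simulated
# cohorts with planted, recoverable disease signatures: class-specific
# mean shifts on intensity-like features of designated nodes
# ("hypometabolism"/"hypermetabolism") and class-specific attenuation or
# amplification of pair-specific latent factors ("edge disruption"/
# "enhancement"), on top of a shared latent-factor model that gives all
# subjects a realistic baseline correlation structure.

synthetic_feature_catalogue <- function() {
  first <- c("Mean", "Median", "Energy", "TotalEnergy", "Entropy", "Minimum",
             "Maximum", "RootMeanSquared", "Skewness", "Kurtosis")
  glcm <- c("JointAverage", "SumAverage", "Contrast", "Correlation",
            "JointEnergy", "JointEntropy", "Idm", "Idn", "ClusterShade",
            "ClusterProminence", "Imc1", "Imc2")
  glrlm <- c("ShortRunEmphasis", "LongRunEmphasis", "GrayLevelNonUniformity",
             "GrayLevelNonUniformityNormalized", "RunLengthNonUniformity",
             "RunPercentage", "LowGrayLevelRunEmphasis",
             "HighGrayLevelRunEmphasis")
  glszm <- c("SmallAreaEmphasis", "LargeAreaEmphasis", "ZoneEntropy",
             "ZonePercentage", "SizeZoneNonUniformity",
             "SizeZoneNonUniformityNormalized")
  ngtdm <- c("Coarseness", "Contrast", "Busyness", "Strength")
  names_all <- c(paste0("firstorder_", first), paste0("glcm_", glcm),
                 paste0("glrlm_", glrlm), paste0("glszm_", glszm),
                 paste0("ngtdm_", ngtdm))
  # exact affine copies of earlier features, as in real radiomic
  # catalogues (e.g. total energy is voxel-volume-scaled energy); they
  # exercise the collinearity pruning
  copies <- tibble::tibble(
    copy = c("firstorder_TotalEnergy", "glcm_SumAverage",
             "glrlm_GrayLevelNonUniformityNormalized",
             "glszm_SizeZoneNonUniformityNormalized"),
    source = c("firstorder_Energy", "glcm_JointAverage",
               "glrlm_GrayLevelNonUniformity", "glszm_SizeZoneNonUniformity"),
    a = c(8.0, 2.0, 0.25, 0.04), b = c(0, 0, 0, 0)
  )
  # intensity-like block carrying the planted metabolic mean shifts
  block <- paste0("firstorder_", c("Mean", "Median", "Energy", "Minimum",
                                   "Maximum", "RootMeanSquared"))
  list(names = names_all, copies = copies, intensity_block = block)
}

sig_edges <- function(atlas, pairs) {
  idx <- function(nm) {
    i <- match(nm, atlas$name)
    if (anyNA(i)) abort(sprintf("unknown region: %s", nm[is.na(i)][1]))
    i
  }
  cbind(idx(pairs[, 1]), idx(pairs[, 2]))
}

#' Planted disease signatures bundled with the generator
#'
#' Three presets loosely emulating the published group-level patterns,
#' mapped onto the bundled atlas: an IPD-like signature (putamen/pallidum
#' hypometabolism, basal-ganglia-thalamic edge disruption, default-mode
#' hyperconnectivity), an MSA-like signature (cerebellar hypometabolism,
#' cerebellar-brainstem decoupling, thalamo-motor enhancement) and a
#' PSP-like signature (midbrain/subthalamic/prefrontal hypometabolism and
#' midbrain-prefrontal disconnection).
#'
#' @param atlas atlas tibble.
#' @return Named list of `planted_signature` objects (one per class),
#'   each holding `hypo_nodes`, `hyper_nodes` (atlas indices),
#'   `disrupted_edges`, `enhanced_edges` (two-column index matrices).
#' @export
default_signatures <- function(atlas = default_atlas()) {
  validate_atlas(atlas)
  idx <- function(nm) {
    i <- match(nm, atlas$name)
    if (anyNA(i)) abort(sprintf("unknown region: %s", nm[is.na(i)][1]))
    i
  }
  mk <- function(class, hypo, hyper, disrupted, enhanced) {
    sig <- list(class = class, hypo_nodes = idx(hypo),
                hyper_nodes = idx(hyper),
                disrupted_edges = sig_edges(atlas, disrupted),
                enhanced_edges = sig_edges(atlas, enhanced))
    if (length(intersect(sig$hypo_nodes, sig$hyper_nodes))) {
      abort("hypo and hyper node sets must be disjoint")
    }
    structure(sig, class = "planted_signature")
  }
  list(
    IPD = mk(
      "IPD",
      hypo = c("Putamen_L", "Putamen_R", "Pallidum_Int_L", "Pallidum_Int_R"),
      hyper = c("Cingulum_Post_L", "Cingulum_Post_R", "Precuneus_L",
                "Precuneus_R"),
      disrupted = rbind(c("Putamen_L", "Thalamus_L"),
                        c("Putamen_R", "Thalamus_R"),
                        c("Pallidum_Int_L", "Thalamus_L"),
                        c("Pallidum_Int_R", "Thalamus_R"),
                        c("Caudate_L", "Putamen_L"),
                        c("Caudate_R", "Putamen_R")),
      enhanced = rbind(c("Cingulum_Post_L", "Precuneus_L"),
                       c("Cingulum_Post_R", "Precuneus_R"),
                       c("Cingulum_Post_L", "Postcentral_L"))
    ),
    MSA = mk(
      "MSA",
      hypo = c("Cerebelum_Crus1_L", "Cerebelum_Crus1_R", "Cerebelum_VI_L",
               "Cerebelum_VI_R", "Vermis_VI", "Vermis_VIII"),
      hyper = c("Supp_Motor_Area_L", "Supp_Motor_Area_R"),
      disrupted = rbind(c("Cerebelum_VI_L", "Red_Nucleus_L"),
                        c("Cerebelum_VI_R", "Red_Nucleus_R"),
                        c("Cerebelum_Crus1_L", "Thalamus_L"),
                        c("Cerebelum_Crus1_R", "Thalamus_R"),
                        c("Vermis_VI", "Vermis_VIII")),
      enhanced = rbind(c("Thalamus_L", "Supp_Motor_Area_L"),
                       c("Thalamus_R", "Supp_Motor_Area_R"))
    ),
    PSP = mk(
      "PSP",
      hypo = c("Substantia_Nigra_L", "Substantia_Nigra_R",
               "Subthalamic_Nucleus_L", "Subthalamic_Nucleus_R",
               "Red_Nucleus_L", "Red_Nucleus_R", "Frontal_Mid_L",
               "Frontal_Mid_R"),
      hyper = c("Parietal_Sup_L", "Parietal_Sup_R"),
      disrupted = rbind(c("Substantia_Nigra_L", "Frontal_Mid_L"),
                        c("Substantia_Nigra_R", "Frontal_Mid_R"),
                        c("Red_Nucleus_L", "Frontal_Sup_L"),
                        c("Red_Nucleus_R", "Frontal_Sup_R"),
                        c("Subthalamic_Nucleus_L", "Substantia_Nigra_L"),
                        c("Subthalamic_Nucleus_R", "Substantia_Nigra_R")),
      enhanced = rbind(c("Parietal_Inf_L", "Frontal_Mid_L"),
                       c("Parietal_Inf_R", "Frontal_Mid_R"))
    )
  )
}

#' Synthetic cohort specification
#'
#' Fixes the generative conditions: per-class sample size, the feature
#' catalogue (40 columns of which 4 are exact affine copies, so pruning
#' retains 36), the latent-factor structure producing baseline
#' inter-regional correlations, effect sizes of the planted signatures
#' and the subject noise level.  `effect_scale = 0` yields a null cohort
#' whose class-conditional distributions are identical.
#'
#' @param n_per_class subjects per class.
#' @param signatures named list of signatures (default
#'   [default_signatures()]).
#' @param n_latent number of shared latent factors.
#' @param noise_sd independent noise standard deviation.
#' @param delta_hypo mean shift added to the intensity block of
#'   hypometabolic nodes (negative).
#' @param delta_hyper mean shift for hypermetabolic nodes (positive).
#' @param rho_factor attenuation in `[0, 1)` of the pair-factor loading
#'   on disrupted edges.
#' @param amp_factor amplification (> 1) on enhanced edges.
#' @param effect_scale global effect multiplier in `[0, 1]`; scales the
#'   deltas and pulls `rho_factor`/`amp_factor` toward 1.
#' @param atlas atlas tibble.
#' @param seed cohort seed (subject-level draws).
#' @param structure_seed seed of the population-level structure (regional
#'   baseline profiles, latent loadings, feature scales).  Cohorts that
#'   should be exchangeable -- training and test sets, pretraining and
#'   fine-tuning sets -- must share it; it defaults to a fixed constant
#'   precisely so that different cohort seeds sample the same population.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_per_class = 50L, signatures = NULL,
                        n_latent = 5L, noise_sd = 0.6,
                        delta_hypo = -1.5, delta_hyper = 1.0,
                        rho_factor = 0.35, amp_factor = 1.5,
                        effect_scale = 1.0, atlas = default_atlas(),
                        seed = 1L, structure_seed = 101L) {
  if (n_per_class < 2L) abort("n_per_class must be at least 2")
  if (noise_sd <= 0) abort("noise_sd must be positive")
  if (rho_factor < 0 || rho_factor >= 1) abort("rho_factor must be in [0, 1)")
  validate_atlas(atlas)
  signatures <- signatures %||% default_signatures(atlas)
  structure(
    list(n_per_class = as.integer(n_per_class), signatures = signatures,
         n_latent = as.integer(n_latent), noise_sd = noise_sd,
         delta_hypo = delta_hypo, delta_hyper = delta_hyper,
         rho_factor = rho_factor, amp_factor = amp_factor,
         effect_scale = effect_scale, atlas = atlas,
         seed = as.integer(seed),
         structure_seed = as.integer(structure_seed)),
    class = "cohort_spec"
  )
}

# population-level fixed structure, deterministic in spec$structure_seed
# (not the cohort seed, so train/test cohorts share it): regional
# baseline profiles, latent-factor loadings, feature scales and the
# catalogue of tracked (pair-factor) edges
cohort_structure <- function(spec) {
  cat36 <- synthetic_feature_catalogue()
  real_names <- setdiff(cat36$names, cat36$copies$copy)
  F0 <- length(real_names)
  n <- nrow(spec$atlas)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$structure_seed)
  M <- matrix(rnorm(n * F0), n, F0)                  # regional baselines
  Lambda <- matrix(rnorm(n * spec$n_latent, 0, 0.7), n, spec$n_latent)
  scale_f <- runif(F0, 0.5, 2)                       # feature scales
  offset_f <- rnorm(F0, 0, 2)
  pairs <- unique(do.call(rbind, lapply(spec$signatures, function(s) {
    rbind(s$disrupted_edges, s$enhanced_edges)
  })))
  list(M = M, Lambda = Lambda, scale_f = scale_f, offset_f = offset_f,
       real_names = real_names, F0 = F0, catalogue = cat36,
       pairs = pairs, pair_loading = 1.1)
}

#' Generate one synthetic subject
#'
#' Draws a subject from the latent-factor model under a class signature:
#' shared factors give baseline inter-regional correlation, dedicated
#' pair factors give the tracked edges extra coupling which the class's
#' `rho_factor`/`amp_factor` attenuates or amplifies, mean shifts are
#' added to the intensity block of affected nodes, and the affine-copy
#' columns are appended last.  Uses the current RNG stream; seed the
#' caller for reproducibility.
#'
#' @param spec a [cohort_spec()].
#' @param class class label, a name of `spec$signatures`.
#' @param subject_id subject identifier.
#' @param structure precomputed [cohort_structure] (internal reuse).
#' @return A labelled [radiomic_table()].
#' @export
generate_subject <- function(spec, class, subject_id = class,
                             structure = NULL) {
  if (!class %in% names(spec$signatures)) {
    abort(sprintf("class %s not in spec signatures", class))
  }
  st <- structure %||% cohort_structure(spec)
  sig <- spec$signatures[[class]]
  n <- nrow(spec$atlas); F0 <- st$F0
  es <- spec$effect_scale
  X <- st$M + st$Lambda %*% matrix(rnorm(spec$n_latent * F0), ncol = F0)
  # pair-specific factors: shared by both endpoints, scaled by the
  # class's disruption/enhancement for that pair
  d_keys <- paste(sig$disrupted_edges[, 1], sig$disrupted_edges[, 2])
  e_keys <- paste(sig$enhanced_edges[, 1], sig$enhanced_edges[, 2])
  rho_eff <- 1 - (1 - spec$rho_factor) * es
  amp_eff <- 1 + (spec$amp_factor - 1) * es
  for (p in seq_len(nrow(st$pairs))) {
    i <- st$pairs[p, 1]; j <- st$pairs[p, 2]
    key <- paste(i, j)
    mult <- if (key %in% d_keys) rho_eff else if (key %in% e_keys) amp_eff else 1
    gam <- rnorm(F0)
    X[i, ] <- X[i, ] + st$pair_loading * mult * gam
    X[j, ] <- X[j, ] + st$pair_loading * mult * gam
  }
  block <- match(st$catalogue$intensity_block, st$real_names)
  if (es > 0) {
    X[sig$hypo_nodes, block] <- X[sig$hypo_nodes, block] +
      spec$delta_hypo * es
    X[sig$hyper_nodes, block] <- X[sig$hyper_nodes, block] +
      spec$delta_hyper * es
  }
  X <- X + spec$noise_sd * matrix(rnorm(n * F0), n, F0)
  X <- sweep(sweep(X, 2L, st$scale_f, "*"), 2L, st$offset_f, "+")
  colnames(X) <- st$real_names
  # append the exact affine copies
  cp <- st$catalogue$copies
  full <- cbind(X, vapply(seq_len(nrow(cp)), function(k) {
    cp$a[k] * X[, cp$source[k]] + cp$b[k]
  }, numeric(n)))
  colnames(full) <- c(st$real_names, cp$copy)
  full <- full[, st$catalogue$names] # catalogue order
  radiomic_table(full, colnames(full), subject_id = subject_id,
                 label = class, atlas = spec$atlas)
}

#' Generate a labelled synthetic cohort with exported ground truth
#'
#' @param spec a [cohort_spec()].
#' @return A `pds_cohort`: `tables` (list of labelled
#'   [radiomic_table()]), `truth` (the planted signatures per class) and
#'   the `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  st <- cohort_structure(spec)
  tables <- list()
  for (cl in names(spec$signatures)) {
    for (s in seq_len(spec$n_per_class)) {
      tables[[length(tables) + 1L]] <-
        generate_subject(spec, cl, sprintf("%s_%03d", cl, s), structure = st)
    }
  }
  structure(list(tables = tables, truth = spec$signatures, spec = spec),
            class = "pds_cohort")
}

#' @export
print.pds_cohort <- function(x, ...) {
  cat(sprintf("<pds_cohort> %d subjects (%d classes x %d), %d features\n",
              length(x$tables), length(x$spec$signatures),
              x$spec$n_per_class, ncol(x$tables[[1]]$values)))
  invisible(x)
}

#' Write the planted ground truth as JSON
#'
#' Machine-readable export of the per-class signatures (node indices and
#' edge pairs), consumed by explainer-recovery checks.
#'
#' @param cohort a `pds_cohort`.
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
ground_truth_report <- function(cohort, path) {
  truth <- lapply(cohort$truth, function(s) {
    list(class = s$class,
         hypo_nodes = s$hypo_nodes, hyper_nodes = s$hyper_nodes,
         disrupted_edges = unname(s$disrupted_edges),
         enhanced_edges = unname(s$enhanced_edges))
  })
  jsonlite::write_json(truth, path, auto_unbox = TRUE)
  invisible(path)
}

#' Read a ground-truth report
#'
#' @param path JSON file from [ground_truth_report()].
#' @return Named list of signatures (node index vectors and edge
#'   matrices).
#' @export
read_ground_truth <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(raw, function(s) {
    list(class = s$class,
         hypo_nodes = as.integer(s$hypo_nodes),
         hyper_nodes = as.integer(s$hyper_nodes),
         disrupted_edges = matrix(as.integer(s$disrupted_edges), ncol = 2),
         enhanced_edges = matrix(as.integer(s$enhanced_edges), ncol = 2))
  })
}

#' Write a cohort to a directory of feature tables
#'
#' Emits one CSV per subject, a `labels.tsv` file and the ground-truth
#' JSON; the directory is readable back with [read_cohort_dir()].
#'
#' @param cohort a `pds_cohort`.
#' @param path output directory.
#' @return `path`, invisibly.
#' @export
write_cohort_dir <- function(cohort, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  for (t in cohort$tables) {
    write_feature_table(t, file.path(path, paste0(t$subject_id, ".csv")))
  }
  labels <- tibble::tibble(
    subject_id = vapply(cohort$tables, `[[`, character(1), "subject_id"),
    label = vapply(cohort$tables, `[[`, character(1), "label")
  )
  readr::write_tsv(labels, file.path(path, "labels.tsv"))
  ground_truth_report(cohort, file.path(path, "truth.json"))
  write_atlas(cohort$spec$atlas, file.path(path, "atlas.tsv"))
  invisible(path)
}

#' Read a cohort directory written by [write_cohort_dir()]
#'
#' @param path cohort directory.
#' @param atlas atlas; read from the bundled `atlas.tsv` when present.
#' @return List with `tables` and `labels` tibble.
#' @export
read_cohort_dir <- function(path, atlas = NULL) {
  af <- file.path(path, "atlas.tsv")
  atlas <- atlas %||% if (file.exists(af)) read_atlas(af) else default_atlas()
  labels <- readr::read_tsv(file.path(path, "labels.tsv"),
                            col_types = "cc")
  tables <- lapply(seq_len(nrow(labels)), function(i) {
    read_feature_table(file.path(path, paste0(labels$subject_id[i], ".csv")),
                       atlas = atlas, subject_id = labels$subject_id[i],
                       label = labels$label[i])
  })
  list(tables = tables, labels = labels)
}
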