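#' Specification of a synthetic resting-state cohort
#'
#' Defines the study design emulated by [generate_cohort()]: a three-group
#' case-control resting-state cohort (healthy controls plus two patient
#' subtypes) observed through ROI-level BOLD time series with a modular
#' (block-structured) correlation architecture, six-parameter head-motion
#' traces, and bounded psychometric/symptom scales. Defaults reproduce the
#' emulated study design: 43/42/41 subjects, 246 nodes in seven functional
#' modules of sizes 50/50/48/21/22/27/28, 195 usable frames at TR = 2 s,
#' and group-wise psychometric means and standard errors taken from the
#' cohort's demographic table.
#'
#' @param group_sizes named integer vector of subjects per group, in the
#'   order HC, FCNAD, FCAD.
#' @param n_nodes number of atlas regions (nodes).
#' @param module_sizes ordered community sizes; must sum to `n_nodes`.
#' @param module_names one short name per module.
#' @param n_frames usable frames per subject.
#' @param tr_seconds repetition time in seconds.
#' @param within_r,between_r baseline Pearson correlation inside and
#'   between modules.
#' @param effect_map list of planted group effects, see [cohort_effect()].
#'   `NULL` gives the default patient effects; `list()` disables planting.
#' @param psychometric_spec data frame with columns `scale`, `group`,
#'   `mean`, `se`, `lo`, `hi` (see `default_psychometrics()`).
#' @param gender_counts 3x2 matrix of male/female counts per group
#'   (drawn exactly, not binomially, so the gender chi-square worked
#'   example is reproducible).
#' @param baseline_signal mean BOLD signal level (arbitrary units) added
#'   to the zero-mean fluctuations; sets the DVARS denominator.
#' @param drift_sd standard deviation of the per-node linear drift slope
#'   (units per scan) exercising the detrending step.
#' @param n_spikes number of motion/signal spike frames per subject.
#' @param spike_mm translation spike amplitude in mm.
#' @param spike_bold BOLD offset (signal units) at spike frames.
#' @param seed master integer seed; every subject draws from a derived
#'   sub-seed so generation is reproducible and order-independent.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(group_sizes = c(HC = 43L, FCNAD = 42L, FCAD = 41L),
                        n_nodes = 246L,
                        module_sizes = c(50L, 50L, 48L, 21L, 22L, 27L, 28L),
                        module_names = c("FPN", "SN", "DMN", "LIM",
                                         "VIS", "SMN", "BG"),
                        n_frames = 195L,
                        tr_seconds = 2,
                        within_r = 0.3,
                        between_r = 0.05,
                        effect_map = NULL,
                        psychometric_spec = default_psychometrics(),
                        gender_counts = default_gender_counts(),
                        baseline_signal = 1000,
                        drift_sd = 2,
                        n_spikes = 3L,
                        spike_mm = 2,
                        spike_bold = 10,
                        seed = 20210311L) {
  stop_if_not(length(group_sizes) == 3L && all(group_sizes > 0),
              "group_sizes must be three positive counts")
  if (is.null(names(group_sizes))) names(group_sizes) <- c("HC", "FCNAD", "FCAD")
  stop_if_not(sum(module_sizes) == n_nodes,
              "module_sizes sum to %d but n_nodes is %d",
              sum(module_sizes), n_nodes)
  stop_if_not(length(module_names) == length(module_sizes),
              "one module name per module size required")
  stop_if_not(abs(within_r) < 1 && abs(between_r) < 1,
              "|within_r| and |between_r| must be < 1")
  stop_if_not(n_frames >= 10, "n_frames too small")
  stop_if_not(tr_seconds > 0, "tr_seconds must be positive")
  stop_if_not(all(psychometric_spec$se > 0), "psychometric SEs must be positive")
  if (is.null(effect_map)) effect_map <- default_effect_map()
  ## adapt gender counts to non-default group sizes, keeping the male
  ## fraction of each row
  for (k in 1:3) {
    if (sum(gender_counts[k, ]) != group_sizes[k]) {
      m <- round_half_up(group_sizes[k] * gender_counts[k, 1L] /
                           sum(gender_counts[k, ]))
      gender_counts[k, ] <- c(m, group_sizes[k] - m)
    }
  }
  spec <- structure(
    list(group_sizes = as.integer(group_sizes),
         groups = names(group_sizes),
         n_nodes = as.integer(n_nodes),
         module_sizes = as.integer(module_sizes),
         module_names = module_names,
         n_frames = as.integer(n_frames),
         tr_seconds = tr_seconds,
         within_r = within_r,
         between_r = between_r,
         effect_map = effect_map,
         psychometric_spec = psychometric_spec,
         gender_counts = gender_counts,
         baseline_signal = baseline_signal,
         drift_sd = drift_sd,
         n_spikes = as.integer(n_spikes),
         spike_mm = spike_mm,
         spike_bold = spike_bold,
         seed = as.integer(seed)),
    class = "cohort_spec")
  names(spec$group_sizes) <- spec$groups
  spec
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Synthetic resting-state cohort specification\n")
  cat(sprintf("  groups: %s\n",
              paste(sprintf("%s=%d", x$groups, x$group_sizes), collapse = " ")))
  cat(sprintf("  nodes: %d in %d modules (%s)\n", x$n_nodes,
              length(x$module_sizes), paste(x$module_sizes, collapse = "/")))
  cat(sprintf("  frames: %d at TR = %gs; within_r = %g, between_r = %g\n",
              x$n_frames, x$tr_seconds, x$within_r, x$between_r))
  cat(sprintf("  planted effects: %d; seed: %d\n",
              length(x$effect_map), x$seed))
  invisible(x)
}

#' A planted group effect on the target correlation structure
#'
#' Three effect types are supported. `"smallworld"` scales all
#' within-module correlations by `within_scale` and adds `between_add` to
#' all between-module correlations, flattening the modular contrast and
#' thereby lowering normalized clustering and small-world-ness in the
#' affected groups. `"node_scale"` scales every correlation involving the
#' nodes in `nodes` by `scale` (equivalent to a diagonal congruence with
#' the diagonal reset to one, hence positive-definiteness is preserved),
#' lowering those nodes' degree and efficiency. `"block_add"` adds
#' `delta` to the correlations between two named modules, raising their
#' inter-module connectivity.
#'
#' @param type one of `"smallworld"`, `"node_scale"`, `"block_add"`.
#' @param groups group labels the effect applies to.
#' @param within_scale,between_add smallworld-effect parameters.
#' @param nodes integer node indices or `"key_regions"` (the designated
#'   rACC/thalamus nodes of the synthetic atlas).
#' @param scale node-scale factor in (0, 1].
#' @param modules length-2 vector of module names or indices.
#' @param delta correlation increment for the module pair.
#' @return a list describing the effect, class `cohort_effect`.
#' @export
cohort_effect <- function(type = c("smallworld", "node_scale", "block_add"),
                          groups = c("FCNAD", "FCAD"),
                          within_scale = 1, between_add = 0,
                          nodes = "key_regions", scale = 1,
                          modules = c("SN", "SMN"), delta = 0) {
  type <- match.arg(type)
  structure(list(type = type, groups = groups,
                 within_scale = within_scale, between_add = between_add,
                 nodes = nodes, scale = scale,
                 modules = modules, delta = delta),
            class = "cohort_effect")
}

#' Default planted patient effects
#'
#' Both patient groups receive (i) a flattened modular contrast lowering
#' normalized clustering and small-world-ness, (ii) weakened connectivity
#' of the designated rACC/thalamus nodes, and (iii) increased
#' salience-sensorimotor (SN-SMN) inter-module connectivity.
#'
#' @return list of `cohort_effect` objects.
#' @export
default_effect_map <- function() {
  list(
    cohort_effect("smallworld", within_scale = 0.75, between_add = 0.035),
    cohort_effect("node_scale", nodes = "key_regions", scale = 0.7),
    cohort_effect("block_add", modules = c("SN", "SMN"), delta = 0.10)
  )
}

#' Group-wise psychometric and symptom distributions
#'
#' Mean and standard error per group for the depression (SDS), anxiety
#' (SAS), and state/trait anxiety (SAI/TAI) scales, the four
#' constipation-symptom ratings (patients only), and age. Standard
#' deviations are recovered as SE * sqrt(n). Scale draws are truncated to
#' `[lo, hi]`; symptom draws are clipped to [0, 100].
#'
#' @return data frame with columns scale, group, mean, se, lo, hi.
#' @export
default_psychometrics <- function() {
  tab <- rbind(
    c("sds",  "HC", 37.3953, 1.1780), c("sds",  "FCNAD", 44.7857, 1.0710),
    c("sds",  "FCAD", 69.0244, 1.4673),
    c("sas",  "HC", 33.4884, 1.0462), c("sas",  "FCNAD", 41.3810, 1.0421),
    c("sas",  "FCAD", 63.7073, 1.5801),
    c("sai",  "HC", 28.3256, 1.2325), c("sai",  "FCNAD", 33.6667, 1.5406),
    c("sai",  "FCAD", 57.3415, 1.5176),
    c("tai",  "HC", 30.0465, 1.1489), c("tai",  "FCNAD", 36.3571, 1.4301),
    c("tai",  "FCAD", 55.2439, 1.2854),
    c("age",  "HC", 38.0698, 2.0942), c("age",  "FCNAD", 42.7619, 2.0774),
    c("age",  "FCAD", 38.6098, 1.8044),
    c("difficulty_defecation",   "FCNAD", 67.9762, 3.1373),
    c("difficulty_defecation",   "FCAD",  71.6585, 3.6181),
    c("incomplete_evacuation",   "FCNAD", 63.7619, 3.9184),
    c("incomplete_evacuation",   "FCAD",  65.5366, 4.8007),
    c("abdominal_distension",    "FCNAD", 44.6429, 4.6566),
    c("abdominal_distension",    "FCAD",  63.5122, 4.6608),
    c("abdominal_pain",          "FCNAD", 25.7857, 3.6878),
    c("abdominal_pain",          "FCAD",  34.9024, 4.6353))
  out <- data.frame(scale = tab[, 1L], group = tab[, 2L],
                    mean = as.numeric(tab[, 3L]), se = as.numeric(tab[, 4L]),
                    stringsAsFactors = FALSE)
  rng <- function(s) switch(s,
    age = c(18, 75),
    sds = , sas = , sai = , tai = c(20, 80),
    c(0, 100))
  lim <- t(vapply(out$scale, rng, numeric(2L)))
  out$lo <- lim[, 1L]; out$hi <- lim[, 2L]
  out
}

#' @rdname default_psychometrics
#' @export
default_gender_counts <- function() {
  m <- matrix(c(18L, 25L, 16L, 26L, 10L, 31L), nrow = 3L, byrow = TRUE,
              dimnames = list(c("HC", "FCNAD", "FCAD"), c("M", "F")))
  m
}

#' Synthetic atlas node table
#'
#' Assigns each node a label and a module. A few nodes carry the names of
#' regions the pipeline's worked examples refer to (rostral anterior
#' cingulate and thalamus as the weakened "key regions", plus
#' pre/postcentral and insular nodes); all are synthetic stand-ins, not
#' anatomical coordinates.
#'
#' @param spec a [cohort_spec()].
#' @return data frame with columns `node`, `label`, `module`.
#' @export
make_atlas <- function(spec) {
  module <- rep(spec$module_names, spec$module_sizes)
  label <- sprintf("R%03d", seq_len(spec$n_nodes))
  atlas <- data.frame(node = seq_len(spec$n_nodes), label = label,
                      module = module, stringsAsFactors = FALSE)
  name_first <- function(mod, names) {
    avail <- which(atlas$module == mod)
    k <- min(length(avail), length(names))
    atlas$label[avail[seq_len(k)]] <<- names[seq_len(k)]
  }
  if (all(c("SN", "SMN", "BG", "DMN") %in% spec$module_names)) {
    name_first("SN",  c("rACC_L", "rACC_R", "dACC_L", "aINS_L", "aINS_R",
                        "pINS_L"))
    name_first("BG",  c("THA_L", "THA_R"))
    name_first("SMN", c("PreCen_L", "PreCen_R", "PostCen_L", "SMA_L",
                        "SMA_R"))
    name_first("DMN", c("DMPFC"))
  }
  atlas
}

#' Designated key-region nodes (rACC + thalamus) of the synthetic atlas
#' @param spec a [cohort_spec()].
#' @return integer node indices.
#' @export
key_region_nodes <- function(spec) {
  atlas <- make_atlas(spec)
  which(atlas$label %in% c("rACC_L", "rACC_R", "THA_L", "THA_R"))
}

## Baseline block correlation matrix: within_r inside modules,
## between_r elsewhere, unit diagonal.
base_correlation <- function(spec) {
  mod <- rep(seq_along(spec$module_sizes), spec$module_sizes)
  same <- outer(mod, mod, "==")
  R <- ifelse(same, spec$within_r, spec$between_r)
  diag(R) <- 1
  R
}

## Apply one planted effect to a correlation matrix.
apply_effect <- function(R, eff, spec) {
  mod <- rep(seq_along(spec$module_sizes), spec$module_sizes)
  off <- !diag(nrow(R))
  if (eff$type == "smallworld") {
    same <- outer(mod, mod, "==") & off
    R[same] <- R[same] * eff$within_scale
    R[!outer(mod, mod, "==")] <- R[!outer(mod, mod, "==")] + eff$between_add
  } else if (eff$type == "node_scale") {
    nodes <- eff$nodes
    if (identical(nodes, "key_regions")) nodes <- key_region_nodes(spec)
    hit <- outer(seq_len(nrow(R)) %in% nodes, seq_len(nrow(R)) %in% nodes, "|") & off
    R[hit] <- R[hit] * eff$scale
  } else if (eff$type == "block_add") {
    midx <- eff$modules
    if (is.character(midx)) midx <- match(midx, spec$module_names)
    stop_if_not(!anyNA(midx) && length(midx) == 2L,
                "block_add effect needs two valid modules")
    pair <- (outer(mod == midx[1L], mod == midx[2L], "&") |
             outer(mod == midx[2L], mod == midx[1L], "&"))
    R[pair] <- R[pair] + eff$delta
  }
  R
}

#' Target correlation matrix for one group
#'
#' Builds the block-structured baseline and applies all planted effects
#' whose group list contains `group`. If the perturbed matrix is not
#' positive definite it is repaired by clipping eigenvalues at 1e-6 and
#' renormalizing to unit diagonal, with a warning.
#'
#' @param spec a [cohort_spec()].
#' @param group group label.
#' @return correlation matrix (n_nodes x n_nodes).
#' @export
group_correlation <- function(spec, group) {
  R <- base_correlation(spec)
  for (eff in spec$effect_map) {
    if (group %in% eff$groups) R <- apply_effect(R, eff, spec)
  }
  stop_if_not(all(abs(R[upper.tri(R)]) < 1),
              "planted effects pushed a correlation outside (-1, 1)")
  ev <- eigen(R, symmetric = TRUE)
  if (min(ev$values) < 1e-6) {
    warning(sprintf(
      "target correlation for group %s not positive definite (min eigenvalue %.3g); repaired by eigenvalue clipping at 1e-6",
      group, min(ev$values)))
    vals <- pmax(ev$values, 1e-6)
    S <- ev$vectors %*% (vals * t(ev$vectors))
    R <- stats::cov2cor(S)
    R <- (R + t(R)) / 2
  }
  R
}

#' Simulate a six-parameter head-motion trace
#'
#' A small-amplitude random walk over three translations (mm) and three
#' rotations (radians), with large translation displacements injected at
#' `spike_frames` to exercise the scrubbing rule.
#'
#' @param n_frames number of frames.
#' @param spike_frames integer frame indices receiving a spike.
#' @param seed optional integer seed.
#' @param amplitude per-frame random-walk step SD for translations (mm);
#'   rotations use `amplitude / 50` so both contribute comparably to
#'   framewise displacement.
#' @param spike_mm spike amplitude in mm.
#' @return object of class `motion_trace` with fields `params`
#'   (frames x 6) and `fd` (framewise displacement, mm); the `dvars`
#'   field is `NULL` until paired with a time series via
#'   [compute_dvars()].
#' @export
generate_motion <- function(n_frames, spike_frames = integer(0), seed = NULL,
                            amplitude = 0.01, spike_mm = 2) {
  stop_if_not(all(spike_frames >= 1 & spike_frames <= n_frames),
              "spike_frames out of range")
  if (!is.null(seed)) set.seed(seed)
  step_sd <- rep(c(amplitude, amplitude / 50), each = 3L)
  steps <- matrix(stats::rnorm(n_frames * 6L), n_frames, 6L)
  steps <- sweep(steps, 2L, step_sd, "*")
  steps[1L, ] <- 0
  params <- apply(steps, 2L, cumsum)
  if (n_frames == 1L) params <- matrix(params, 1L, 6L)
  params[spike_frames, 1L] <- params[spike_frames, 1L] + spike_mm
  colnames(params) <- c("tx", "ty", "tz", "rx", "ry", "rz")
  motion_trace(params)
}

#' Construct a motion trace from rigid-body parameters
#' @param params frames x 6 matrix (3 translations mm, 3 rotations rad).
#' @param dvars optional per-frame DVARS vector.
#' @return `motion_trace` object with computed framewise displacement.
#' @export
motion_trace <- function(params, dvars = NULL) {
  structure(list(params = params, fd = compute_fd(params), dvars = dvars),
            class = "motion_trace")
}

#' ROI time-series container
#' @param data frames x nodes signal matrix.
#' @param tr_seconds sampling interval (s).
#' @param subject_id subject identifier.
#' @param valid_mask logical per-frame validity (default all valid).
#' @param wm,csf optional white-matter / CSF nuisance signals.
#' @return object of class `roi_timeseries`.
#' @export
roi_timeseries <- function(data, tr_seconds, subject_id = "S000",
                           valid_mask = rep(TRUE, nrow(data)),
                           wm = NULL, csf = NULL) {
  stop_if_not(tr_seconds > 0, "tr_seconds must be positive")
  stop_if_not(length(valid_mask) == nrow(data),
              "valid_mask length must equal frame count")
  stop_if_not(all(is.finite(data[valid_mask, ])),
              "non-finite values among valid frames")
  structure(list(subject_id = subject_id, data = data,
                 tr_seconds = tr_seconds, valid_mask = valid_mask,
                 wm = wm, csf = csf),
            class = "roi_timeseries")
}

## Truncated-normal draw by rejection; deterministic under the caller's seed.
rtruncnorm <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(x < lo | x > hi)
  }
  x
}

#' Generate a full synthetic cohort
#'
#' Draws, per subject: a frames x nodes BOLD matrix from a zero-mean
#' multivariate Gaussian whose correlation matrix is the group's
#' block-structured target (obtained by a Cholesky factor applied to
#' white noise), plus a baseline signal level, per-node linear drift and
#' spike artifacts; a six-parameter motion trace with matched spike
#' frames; and bounded psychometric/symptom scores (SD taken as
#' SE * sqrt(n), truncated to scale range). Gender is assigned to match
#' the configured counts exactly. Fully deterministic under `spec$seed`.
#'
#' @param spec a [cohort_spec()].
#' @param signals generate BOLD time series and motion traces; set to
#'   `FALSE` for a fast subjects-table-only draw (psychometric studies).
#' @return list with elements `subjects` (data frame), `timeseries`
#'   (list of [roi_timeseries()]), `motion` (list of `motion_trace`),
#'   `atlas`, and `spec`.
#' @export
generate_cohort <- function(spec, signals = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  atlas <- make_atlas(spec)
  groups <- rep(spec$groups, spec$group_sizes)
  n <- length(groups)
  ids <- sprintf("S%03d", seq_len(n))

  ## psychometrics, ages, gender: one derived seed for the whole table
  set.seed(derive_seed(spec$seed, 0L))
  ps <- spec$psychometric_spec
  cols <- c("age", "sds", "sas", "sai", "tai", "difficulty_defecation",
            "incomplete_evacuation", "abdominal_distension", "abdominal_pain")
  tab <- matrix(NA_real_, n, length(cols), dimnames = list(NULL, cols))
  for (g in spec$groups) {
    gi <- which(groups == g)
    ng <- length(gi)
    for (sc in cols) {
      row <- ps[ps$scale == sc & ps$group == g, ]
      if (!nrow(row)) next
      sd_g <- row$se * sqrt(ng)
      if (sc %in% c("age", "sds", "sas", "sai", "tai")) {
        tab[gi, sc] <- rtruncnorm(ng, row$mean, sd_g, row$lo, row$hi)
      } else {
        tab[gi, sc] <- pmin(pmax(stats::rnorm(ng, row$mean, sd_g), row$lo),
                            row$hi)
      }
    }
  }
  gender <- character(n)
  for (k in seq_along(spec$groups)) {
    gi <- which(groups == spec$groups[k])
    gvec <- rep(c("M", "F"), spec$gender_counts[k, ])
    stop_if_not(length(gvec) == length(gi),
                "gender counts for group %s do not match its size",
                spec$groups[k])
    gender[gi] <- sample(gvec)
  }
  subjects <- data.frame(subject_id = ids, group = groups, gender = gender,
                         round(tab, 4L), stringsAsFactors = FALSE)

  if (!signals) {
    return(list(subjects = subjects, timeseries = NULL, motion = NULL,
                atlas = atlas, spec = spec))
  }

  ## group target correlations and their Cholesky factors
  chol_by_group <- lapply(stats::setNames(spec$groups, spec$groups),
                          function(g) chol(group_correlation(spec, g)))

  timeseries <- vector("list", n)
  motion <- vector("list", n)
  tgrid <- seq_len(spec$n_frames)
  for (i in seq_len(n)) {
    set.seed(derive_seed(spec$seed, i))
    spikes <- if (spec$n_spikes > 0)
      sort(sample(seq(5L, spec$n_frames - 5L), spec$n_spikes)) else integer(0)
    Z <- matrix(stats::rnorm(spec$n_frames * spec$n_nodes),
                spec$n_frames, spec$n_nodes)
    X <- Z %*% chol_by_group[[groups[i]]]
    drift <- stats::rnorm(spec$n_nodes, 0, spec$drift_sd)
    X <- X + outer((tgrid - mean(tgrid)) / spec$n_frames, drift)
    X <- X + spec$baseline_signal
    X[spikes, ] <- X[spikes, ] + spec$spike_bold
    wm <- stats::rnorm(spec$n_frames)
    csf <- stats::rnorm(spec$n_frames)
    mt <- generate_motion(spec$n_frames, spikes,
                          seed = derive_seed(spec$seed, 100000L + i),
                          spike_mm = spec$spike_mm)
    mt$dvars <- compute_dvars(X)
    timeseries[[i]] <- roi_timeseries(X, spec$tr_seconds, ids[i],
                                      wm = wm, csf = csf)
    motion[[i]] <- mt
  }
  list(subjects = subjects, timeseries = timeseries, motion = motion,
       atlas = atlas, spec = spec)
}

#' Write a cohort to delimited text files
#'
#' Writes `subjects.tsv`, `atlas.tsv`, one `signals/<id>.tsv` and
#' `motion/<id>.tsv` per subject (frames in rows), nuisance signals in
#' `nuisance/<id>.tsv`, and a JSON manifest recording the seed and design
#' parameters.
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  for (d in file.path(dir, c("", "signals", "motion", "nuisance")))
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, f) utils::write.table(
    x, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(cohort$subjects, "subjects.tsv")
  wt(cohort$atlas, "atlas.tsv")
  for (i in seq_along(cohort$timeseries)) {
    ts <- cohort$timeseries[[i]]
    id <- ts$subject_id
    utils::write.table(round(ts$data, 6L),
                       file.path(dir, "signals", paste0(id, ".tsv")),
                       sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    utils::write.table(round(cohort$motion[[i]]$params, 6L),
                       file.path(dir, "motion", paste0(id, ".tsv")),
                       sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    utils::write.table(round(cbind(wm = ts$wm, csf = ts$csf), 6L),
                       file.path(dir, "nuisance", paste0(id, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  spec <- cohort$spec
  manifest <- list(
    seed = spec$seed, n_nodes = spec$n_nodes, n_frames = spec$n_frames,
    tr_seconds = spec$tr_seconds, group_sizes = as.list(spec$group_sizes),
    module_sizes = spec$module_sizes, module_names = spec$module_names,
    within_r = spec$within_r, between_r = spec$between_r,
    subjects = lapply(seq_len(nrow(cohort$subjects)), function(i) {
      id <- cohort$subjects$subject_id[i]
      list(subject_id = id,
           signals = file.path("signals", paste0(id, ".tsv")),
           motion = file.path("motion", paste0(id, ".tsv")),
           nuisance = file.path("nuisance", paste0(id, ".tsv")))
    }))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#' @param dir cohort directory.
#' @param tr_seconds sampling interval; taken from the manifest if present.
#' @return list with `subjects`, `timeseries`, `motion`, `atlas`.
#' @export
read_cohort <- function(dir, tr_seconds = NULL) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  tr <- tr_seconds %||% man$tr_seconds
  subjects <- utils::read.delim(file.path(dir, "subjects.tsv"),
                                stringsAsFactors = FALSE)
  atlas <- utils::read.delim(file.path(dir, "atlas.tsv"),
                             stringsAsFactors = FALSE)
  timeseries <- list(); motion <- list()
  for (i in seq_len(nrow(subjects))) {
    id <- subjects$subject_id[i]
    X <- as.matrix(utils::read.delim(
      file.path(dir, "signals", paste0(id, ".tsv")), header = FALSE))
    dimnames(X) <- NULL
    nz <- utils::read.delim(file.path(dir, "nuisance", paste0(id, ".tsv")))
    P <- as.matrix(utils::read.delim(
      file.path(dir, "motion", paste0(id, ".tsv")), header = FALSE))
    dimnames(P) <- NULL
    colnames(P) <- c("tx", "ty", "tz", "rx", "ry", "rz")
    mt <- motion_trace(P)
    mt$dvars <- compute_dvars(X)
    timeseries[[i]] <- roi_timeseries(X, tr, id, wm = nz$wm, csf = nz$csf)
    motion[[i]] <- mt
  }
  list(subjects = subjects, timeseries = timeseries, motion = motion,
       atlas = atlas)
}
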