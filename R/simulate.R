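#' Configuration for the synthetic expression generator
#'
#' Encodes the study design the generator emulates: three inbred strains
#' (B = C57BL/6J, N = C57BL/6NJ, D = DBA/2J) by four treatment histories
#' (NH, CMS, NH-R, CMS-R) with 4-5 expression replicates per cell and
#' ~25,858 annotated transcripts. Planted stress-responsive transcripts
#' carry a transient (0:1:0) or sustained (1:1:0) template over
#' (CMS, CMS-R, NH-R) with strain-specific membership blocks, a
#' per-strain up-regulation bias, explicit multi-strain overlap block
#' sizes, and per-pair direction-concordance probabilities.
#'
#' @param n_transcripts number of transcripts (default 25858).
#' @param strains ordered strain labels.
#' @param treatments ordered treatment labels.
#' @param replicates_per_cell samples per strain x treatment cell (>= 2).
#' @param baseline_mean_range log2 range baselines are drawn from.
#' @param residual_sd Gaussian residual SD on the log2 scale.
#' @param effect_size planted template shift in log2 units.
#' @param planted_fraction named per-strain fraction of transcripts
#'   planted exclusively in that strain. Defaults echo the strain-unique
#'   call counts of the motivating design (B ~430, N ~258, D ~1363 of
#'   25,858).
#' @param up_fraction named per-strain probability a planted transcript
#'   is up-regulated (N biased up, D biased down).
#' @param overlap_spec named block sizes for multi-strain regions, names
#'   joining strain labels with ":" (pairs exclusive of the triple).
#' @param concordance_spec named per-strain-pair probability that a
#'   shared transcript responds in the same direction in both strains.
#' @param seed integer seed; all draws flow through it.
#' @return Validated list of class `sim_config`.
#' @export
sim_config <- function(n_transcripts = 25858,
                       strains = c("B", "N", "D"),
                       treatments = c("NH", "CMS", "NH-R", "CMS-R"),
                       replicates_per_cell = 5,
                       baseline_mean_range = c(4, 12),
                       residual_sd = 0.25,
                       effect_size = 1.0,
                       planted_fraction = c(B = 0.017, N = 0.010, D = 0.053),
                       up_fraction = c(B = 0.5, N = 0.7, D = 0.3),
                       overlap_spec = c("B:N" = 9, "B:D" = 31,
                                        "N:D" = 130, "B:N:D" = 6),
                       concordance_spec = c("B:N" = 1.0, "B:D" = 3 / 31,
                                            "N:D" = 15 / 130),
                       seed = 1L) {
  cfg <- list(
    n_transcripts = as.integer(n_transcripts), strains = strains,
    treatments = treatments,
    replicates_per_cell = as.integer(replicates_per_cell),
    baseline_mean_range = baseline_mean_range, residual_sd = residual_sd,
    effect_size = effect_size, planted_fraction = planted_fraction,
    up_fraction = up_fraction, overlap_spec = overlap_spec,
    concordance_spec = concordance_spec, seed = as.integer(seed)
  )
  if (cfg$replicates_per_cell < 2) stop("replicates_per_cell must be >= 2")
  if (cfg$residual_sd <= 0) stop("residual_sd must be > 0")
  if (!all(TEMPLATE_GROUPS %in% treatments) || !"NH" %in% treatments) {
    stop("treatments must include NH, CMS, NH-R, CMS-R")
  }
  if (is.null(names(planted_fraction)) ||
      !setequal(names(planted_fraction), strains)) {
    stop("planted_fraction must be named by strain")
  }
  if (any(planted_fraction < 0 | planted_fraction > 1)) {
    stop("planted fractions must lie in [0, 1]")
  }
  if (any(up_fraction < 0 | up_fraction > 1)) {
    stop("up fractions must lie in [0, 1]")
  }
  if (any(concordance_spec < 0 | concordance_spec > 1)) {
    stop("concordance probabilities must lie in [0, 1]")
  }
  for (r in names(overlap_spec)) {
    rs <- strsplit(r, ":", fixed = TRUE)[[1]]
    if (length(rs) < 2 || !all(rs %in% strains)) {
      stop("overlap_spec region '", r, "' is not a multi-strain region of ",
           paste(strains, collapse = ","))
    }
  }
  planted_total <- sum(overlap_spec) +
    sum(round(planted_fraction[strains] * cfg$n_transcripts))
  if (planted_total > cfg$n_transcripts) {
    stop("overlap_spec and planted fractions exceed n_transcripts (",
         planted_total, " > ", cfg$n_transcripts, ")")
  }
  structure(cfg, class = "sim_config")
}

## draw a direction vector over `strains` for one shared transcript:
## the first strain follows its up-bias, later strains agree with the
## first with the configured pairwise concordance probability.
draw_region_directions <- function(strains, up_fraction, concordance_spec) {
  first <- if (stats::runif(1) < up_fraction[strains[1]]) "UP" else "DOWN"
  dirs <- first
  for (s in strains[-1]) {
    key1 <- paste(strains[1], s, sep = ":")
    key2 <- paste(s, strains[1], sep = ":")
    pr <- if (key1 %in% names(concordance_spec)) concordance_spec[[key1]]
          else if (key2 %in% names(concordance_spec)) concordance_spec[[key2]]
          else 0.5
    agree <- stats::runif(1) < pr
    dirs <- c(dirs, if (agree) first else setdiff(c("UP", "DOWN"), first))
  }
  names(dirs) <- strains
  dirs
}

#' Simulate a log2 expression matrix with planted stress templates
#'
#' Baselines are drawn uniformly over the configured log2 range per
#' transcript; residuals are Gaussian on the log2 scale (the conventional
#' microarray noise model). Planted transcripts have their strain's group
#' means shifted by +/- `effect_size` according to their template over
#' (CMS, CMS-R, NH-R): transient shifts CMS-R only, sustained shifts CMS
#' and CMS-R; the NH group always sits at baseline. Membership blocks are
#' assigned by explicit transcript-index ranges (multi-strain overlap
#' blocks first, then strain-exclusive blocks) so exact region counts are
#' achievable for fixtures.
#'
#' @param config a [sim_config()].
#' @return List: `matrix` (transcripts x samples, log2), `samples`
#'   (sample table), `truth` (data.frame transcript, strain, template,
#'   direction for every planted transcript-strain pair).
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_transcripts
  ids <- sprintf("tx%05d", seq_len(n))

  samples <- expand.grid(
    rep = seq_len(config$replicates_per_cell),
    treatment = config$treatments,
    strain = config$strains,
    stringsAsFactors = FALSE
  )
  samples <- data.frame(
    sample_id = paste(samples$strain, samples$treatment, samples$rep, sep = "_"),
    strain = samples$strain,
    treatment = samples$treatment,
    stringsAsFactors = FALSE
  )

  # membership blocks: multi-strain regions first, then exclusive blocks
  cursor <- 0L
  truth_rows <- list()
  take <- function(size) {
    if (size == 0) return(integer(0))
    idx <- (cursor + 1L):(cursor + size)
    cursor <<- cursor + as.integer(size)
    idx
  }
  for (r in names(config$overlap_spec)) {
    rs <- strsplit(r, ":", fixed = TRUE)[[1]]
    for (i in take(config$overlap_spec[[r]])) {
      dirs <- draw_region_directions(rs, config$up_fraction,
                                     config$concordance_spec)
      tmpl <- sample(TEMPLATE_SHAPES, length(rs), replace = TRUE)
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        transcript = ids[i], strain = rs, template = tmpl,
        direction = unname(dirs), stringsAsFactors = FALSE
      )
    }
  }
  for (s in config$strains) {
    n_excl <- round(config$planted_fraction[[s]] * n)
    idx <- take(n_excl)
    if (length(idx) == 0) next
    dirs <- ifelse(stats::runif(length(idx)) < config$up_fraction[[s]],
                   "UP", "DOWN")
    truth_rows[[length(truth_rows) + 1L]] <- data.frame(
      transcript = ids[idx], strain = s,
      template = sample(TEMPLATE_SHAPES, length(idx), replace = TRUE),
      direction = dirs, stringsAsFactors = FALSE
    )
  }
  truth <- if (length(truth_rows) > 0) {
    do.call(rbind, truth_rows)
  } else {
    data.frame(transcript = character(), strain = character(),
               template = character(), direction = character(),
               stringsAsFactors = FALSE)
  }

  baseline <- stats::runif(n, config$baseline_mean_range[1],
                           config$baseline_mean_range[2])
  mu <- matrix(baseline, nrow = n, ncol = nrow(samples))
  dimnames(mu) <- list(ids, samples$sample_id)
  if (nrow(truth) > 0) {
    for (j in seq_len(nrow(truth))) {
      tr <- truth[j, ]
      shifted_groups <- if (tr$template == "TRANSIENT") "CMS-R" else c("CMS", "CMS-R")
      cols <- samples$sample_id[samples$strain == tr$strain &
                                  samples$treatment %in% shifted_groups]
      sgn <- if (tr$direction == "UP") 1 else -1
      mu[tr$transcript, cols] <- mu[tr$transcript, cols] + sgn * config$effect_size
    }
  }
  noise <- matrix(stats::rnorm(length(mu), sd = config$residual_sd),
                  nrow = n)
  mat <- mu + noise
  list(matrix = mat, samples = samples, truth = truth)
}

#' Configuration for the phenotype and fecal-CORT generators
#'
#' Defaults emulate the printed biometric structure of the motivating
#' design: heart weight ordering D > N > B with a chronic-stress deficit
#' of 10.4 mg; thymus and adrenal orderings N > B > D; brain B ~ N > D;
#' body-weight gain attenuated by CMS in B and N only; plasma CORT higher
#' in N and D after restraint with an N-only cross-sensitization
#' increment in the CMS-R group; baseline fecal CORT means B 1.77, N 1.73,
#' D 1.93 (assay units) with a week-1 elevation that habituates back to
#' baseline by the configured return week.
#'
#' @param group_sizes named animals per treatment per strain (pooled
#'   group sizes land in the printed 12-20 range).
#' @param heart_mean,thymus_mean,adrenal_mean named per-strain organ
#'   weight means (mg); `brain_mean` in g.
#' @param heart_sd,thymus_sd,adrenal_sd,brain_sd residual SDs.
#' @param heart_cms_deficit_mg mean heart-weight loss under CMS exposure
#'   (applied to CMS and CMS-R animals), default 10.4 mg.
#' @param bw_start_mean,bw_start_sd starting body weight (g).
#' @param bw_gain_mean named per-strain weight gain (g) under NH.
#' @param bw_gain_cms_attenuation named per-strain reduction of gain
#'   under CMS exposure (B and N attenuated, D not).
#' @param bw_gain_sd gain residual SD (g).
#' @param cort_restraint_mean named per-strain plasma CORT after acute
#'   restraint (ng/mL); `cort_baseline_mean` at tissue harvest.
#' @param cort_sensitization_cmsr named per-strain additional CORT in the
#'   CMS-R group (cross-sensitization; nonzero for N only by default).
#' @param cort_baseline_cms_increment named per-strain CMS elevation of
#'   harvest CORT.
#' @param cort_restraint_sd,cort_baseline_sd CORT residual SDs.
#' @param fcort_baseline_mean,fcort_baseline_sd named per-strain baseline
#'   fecal CORT metabolite level (assay units).
#' @param fcort_n named animals per strain in the fecal time course.
#' @param fcort_week1_elevation multiplicative week-1 elevation (1 = no
#'   rise).
#' @param fcort_return_week week at which expected fCORT is back to
#'   baseline (1-7).
#' @param seed integer seed.
#' @return Validated list of class `pheno_config`.
#' @export
pheno_config <- function(group_sizes = c("NH" = 7, "NH-R" = 6,
                                         "CMS" = 9, "CMS-R" = 9),
                         heart_mean = c(B = 130, N = 140, D = 165),
                         heart_sd = 8,
                         heart_cms_deficit_mg = 10.4,
                         thymus_mean = c(B = 50, N = 65, D = 35),
                         thymus_sd = 7,
                         adrenal_mean = c(B = 4.6, N = 5.2, D = 3.6),
                         adrenal_sd = 0.5,
                         brain_mean = c(B = 0.470, N = 0.468, D = 0.420),
                         brain_sd = 0.010,
                         bw_start_mean = 18, bw_start_sd = 1,
                         bw_gain_mean = c(B = 3.5, N = 3.5, D = 3.0),
                         bw_gain_cms_attenuation = c(B = 1.5, N = 1.5, D = 0),
                         bw_gain_sd = 1,
                         cort_restraint_mean = c(B = 150, N = 280, D = 290),
                         cort_restraint_sd = 40,
                         cort_sensitization_cmsr = c(B = 0, N = 90, D = 0),
                         cort_baseline_mean = c(B = 40, N = 50, D = 55),
                         cort_baseline_cms_increment = c(B = 25, N = 0, D = 15),
                         cort_baseline_sd = 15,
                         fcort_baseline_mean = c(B = 1.77, N = 1.73, D = 1.93),
                         fcort_baseline_sd = c(B = 0.20, N = 0.27, D = 0.22),
                         fcort_n = c(B = 14, N = 12, D = 13),
                         fcort_week1_elevation = 1.6,
                         fcort_return_week = 4,
                         seed = 1L) {
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  sds <- c(heart_sd, thymus_sd, adrenal_sd, brain_sd, bw_start_sd,
           bw_gain_sd, cort_restraint_sd, cort_baseline_sd,
           fcort_baseline_sd)
  if (any(sds <= 0)) stop("all simulation SDs must be positive")
  means <- c(heart_mean, thymus_mean, adrenal_mean, brain_mean,
             cort_restraint_mean, cort_baseline_mean, fcort_baseline_mean)
  if (any(means <= 0)) stop("all weight and concentration means must be positive")
  if (!(fcort_return_week %in% 1:7)) stop("fcort_return_week must be in 1..7")
  if (fcort_week1_elevation < 1) stop("fcort_week1_elevation must be >= 1")
  if (any(group_sizes < 1)) stop("group sizes must be >= 1")
  structure(cfg, class = "pheno_config")
}

#' Simulate the animal-level phenotype table
#'
#' One row per animal across all strains and the four treatment
#' histories, with body weights, organ weights, plasma CORT and a cyclic
#' sacrifice day. CMS-exposed animals (CMS, CMS-R) draw heart weights
#' with the configured mean deficit and attenuated body-weight gain; the
#' CMS-R cross-sensitization increment and CMS baseline-CORT increments
#' are applied per strain.
#'
#' @param config a [pheno_config()].
#' @return data.frame: `animal_id`, `strain`, `treatment`, `bw_start`,
#'   `bw_end`, `adrenal_mg`, `thymus_mg`, `heart_mg`, `brain_g`,
#'   `plasma_cort`, `sacrifice_day`.
#' @export
simulate_phenotypes <- function(config) {
  stopifnot(inherits(config, "pheno_config"))
  set.seed(config$seed)
  strains <- names(config$heart_mean)
  rows <- list()
  for (s in strains) {
    for (trt in names(config$group_sizes)) {
      ng <- config$group_sizes[[trt]]
      cms <- trt %in% c("CMS", "CMS-R")
      restrained <- trt %in% c("NH-R", "CMS-R")
      bw_start <- stats::rnorm(ng, config$bw_start_mean, config$bw_start_sd)
      gain_mu <- config$bw_gain_mean[[s]] -
        if (cms) config$bw_gain_cms_attenuation[[s]] else 0
      heart_mu <- config$heart_mean[[s]] -
        if (cms) config$heart_cms_deficit_mg else 0
      cort_mu <- if (restrained) {
        config$cort_restraint_mean[[s]] +
          if (trt == "CMS-R") config$cort_sensitization_cmsr[[s]] else 0
      } else {
        config$cort_baseline_mean[[s]] +
          if (trt == "CMS") config$cort_baseline_cms_increment[[s]] else 0
      }
      cort_sd <- if (restrained) config$cort_restraint_sd else config$cort_baseline_sd
      rows[[length(rows) + 1L]] <- data.frame(
        animal_id = paste(s, trt, seq_len(ng), sep = "_"),
        strain = s, treatment = trt,
        bw_start = bw_start,
        bw_end = bw_start + stats::rnorm(ng, gain_mu, config$bw_gain_sd),
        adrenal_mg = stats::rnorm(ng, config$adrenal_mean[[s]], config$adrenal_sd),
        thymus_mg = stats::rnorm(ng, config$thymus_mean[[s]], config$thymus_sd),
        heart_mg = stats::rnorm(ng, heart_mu, config$heart_sd),
        brain_g = stats::rnorm(ng, config$brain_mean[[s]], config$brain_sd),
        plasma_cort = stats::rnorm(ng, cort_mu, cort_sd),
        sacrifice_day = ((seq_len(ng) - 1L) %% 4L) + 1L,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

## expected multiplicative elevation at a given week: peak at week 1,
## linear habituation back to 1 at the return week, flat afterwards.
fcort_multiplier <- function(week, elevation, return_week) {
  if (week < 1 || week >= return_week) return(1)
  if (return_week == 1) return(1)
  1 + (elevation - 1) * (return_week - week) / (return_week - 1)
}

#' Simulate the weekly fecal corticosterone time course
#'
#' Each animal contributes one fCORT measurement per week 0-7 on the
#' natural scale (log transformation belongs to the analysis, not the
#' generator). Week 0 is baseline; the expected level rises by the
#' configured multiplicative elevation at week 1 and habituates linearly
#' back to baseline at the return week, staying there through week 7.
#'
#' @param config a [pheno_config()].
#' @return data.frame: `animal_id`, `strain`, `week`, `fcort`.
#' @export
simulate_fcort_timecourse <- function(config) {
  stopifnot(inherits(config, "pheno_config"))
  set.seed(config$seed + 1L)
  strains <- names(config$fcort_baseline_mean)
  weeks <- 0:7
  rows <- list()
  for (s in strains) {
    n <- config$fcort_n[[s]]
    for (w in weeks) {
      mult <- fcort_multiplier(w, config$fcort_week1_elevation,
                               config$fcort_return_week)
      rows[[length(rows) + 1L]] <- data.frame(
        animal_id = paste0(s, "_fc", seq_len(n)),
        strain = s, week = w,
        fcort = stats::rnorm(n, config$fcort_baseline_mean[[s]] * mult,
                             config$fcort_baseline_sd[[s]]),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Synthetic gene-set collection over simulated transcripts
#'
#' Builds a demonstration GMT-style collection for the end-to-end
#' pipeline: a few sets deliberately enriched in planted transcripts of
#' each strain plus random background sets. Synthetic throughout; not a
#' stand-in for curated annotation databases.
#'
#' @param truth planted-truth table from [simulate_expression()].
#' @param all_ids full transcript universe.
#' @param n_random number of random sets (default 10).
#' @param set_size size of each random set (default 50).
#' @param seed integer seed.
#' @return Named list of id vectors.
#' @export
simulate_gene_sets <- function(truth, all_ids, n_random = 10,
                               set_size = 50, seed = 1L) {
  set.seed(seed)
  sets <- list()
  for (s in unique(truth$strain)) {
    planted <- unique(truth$transcript[truth$strain == s])
    if (length(planted) < 2) next
    core <- sample(planted, min(length(planted), set_size))
    pad <- sample(setdiff(all_ids, core), max(0, set_size - length(core)))
    sets[[paste0("planted_", s, "_module")]] <- c(core, pad)
  }
  for (i in seq_len(n_random)) {
    sets[[sprintf("random_set_%02d", i)]] <- sample(all_ids, set_size)
  }
  sets
}
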