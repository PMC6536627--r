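#' Read a transcript-by-sample expression matrix from TSV
#'
#' First column holds transcript ids, header row holds sample ids.
#' Ragged rows, non-numeric cells and duplicate transcript ids are
#' rejected with the offending line number.
#'
#' @param path TSV path.
#' @return Numeric matrix with transcript rownames and sample colnames.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  fields <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(unique(fields)) > 1) {
    bad <- which(fields != fields[1])[1]
    stop("ragged TSV: line ", bad, " has ", fields[bad],
         " fields, expected ", fields[1])
  }
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  ids <- df[[1]]
  dup <- which(duplicated(ids))
  if (length(dup) > 0) {
    stop("duplicate transcript id '", ids[dup[1]], "' at line ", dup[1] + 1)
  }
  vals <- df[, -1, drop = FALSE]
  num <- suppressWarnings(vapply(vals, as.numeric, numeric(nrow(vals))))
  if (nrow(vals) == 1) num <- matrix(num, nrow = 1, dimnames = list(NULL, names(vals)))
  bad_cell <- which(is.na(num) & !(vals == "NA"), arr.ind = TRUE)
  if (nrow(bad_cell) > 0) {
    stop("non-numeric cell at line ", bad_cell[1, 1] + 1,
         ", column '", colnames(num)[bad_cell[1, 2]], "'")
  }
  if (any(!is.finite(num))) stop("expression matrix contains non-finite values")
  rownames(num) <- ids
  num
}

#' Write an expression matrix as TSV
#'
#' @param mat matrix with transcript rownames and sample colnames.
#' @param path output path.
#' @param id_col name of the id column (default "transcript").
#' @export
write_expression <- function(mat, path, id_col = "transcript") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write the sample metadata sheet
#'
#' CSV with columns `sample_id`, `strain`, `treatment`. Sample ids must
#' be unique; when an expression matrix is supplied every matrix column
#' must be described.
#'
#' @param path CSV path.
#' @param mat optional expression matrix to validate against.
#' @return data.frame sample table.
#' @export
read_samples <- function(path, mat = NULL) {
  if (!file.exists(path)) stop("sample file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "strain", "treatment")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) stop("sample table missing column(s): ",
                             paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids")
  if (!is.null(mat)) {
    orphan <- setdiff(colnames(mat), df$sample_id)
    if (length(orphan) > 0) {
      stop("matrix columns without metadata: ", paste(orphan, collapse = ", "))
    }
  }
  df
}

#' @rdname read_samples
#' @param samples sample table to write.
#' @export
write_samples <- function(samples, path) {
  utils::write.csv(samples, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML path.
#' @return Named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  yaml::read_yaml(path)
}

#' @rdname read_config
#' @param config named list to serialize.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

## write a table atomically: to a temp file in the same directory, then
## rename into place.
write_tsv_atomic <- function(df, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  utils::write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  file.rename(tmp, path)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' End-to-end driver: reads (or simulates) the expression matrix, sample
#' table, phenotype and fecal-CORT tables and gene sets, runs the
#' template-pattern calls, direction-bias tests, overlap partition,
#' pairwise/triple concordance, hierarchical clustering, phenotype and
#' fCORT ANOVAs and over-representation analysis, and writes all result
#' tables plus a machine-readable manifest to the output directory.
#' Tables are written atomically; the manifest records the configuration,
#' package version, seed and per-file status.
#'
#' @param config named list (see [read_config()]): `out` (directory),
#'   `seed`, thresholds `alpha` (default 0.05), `fc` (0.10), `outlier_k`
#'   (2), `min_category` (5); either file paths `expression`, `samples`,
#'   `phenotypes`, `fcort`, `gmt`, or `simulate: TRUE` with optional
#'   `n_transcripts` to generate them.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  out_dir <- config$out
  if (is.null(out_dir)) stop("config$out (output directory) is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  alpha <- config$alpha %||% 0.05
  fc <- config$fc %||% 0.10
  min_cat <- config$min_category %||% 5
  seed <- as.integer(config$seed %||% 1L)

  if (isTRUE(config$simulate)) {
    scfg <- sim_config(n_transcripts = config$n_transcripts %||% 2000,
                       seed = seed)
    sim <- simulate_expression(scfg)
    mat <- sim$matrix
    samples <- sim$samples
    pcfg <- pheno_config(seed = seed)
    pheno <- simulate_phenotypes(pcfg)
    fcort <- simulate_fcort_timecourse(pcfg)
    sets <- simulate_gene_sets(sim$truth, rownames(mat), seed = seed)
  } else {
    for (f in c("expression", "samples", "phenotypes", "fcort", "gmt")) {
      if (is.null(config[[f]])) stop("config is missing path: ", f)
      if (!file.exists(config[[f]])) stop("input file not found: ", config[[f]])
    }
    mat <- read_expression(config$expression)
    samples <- read_samples(config$samples, mat)
    pheno <- utils::read.csv(config$phenotypes, stringsAsFactors = FALSE)
    fcort <- utils::read.csv(config$fcort, stringsAsFactors = FALSE)
    sets <- read_gmt(config$gmt)
  }

  files <- character(0)
  emit <- function(df, name) {
    write_tsv_atomic(df, file.path(out_dir, name))
    files <<- c(files, name)
  }

  calls <- call_stress_transcripts(mat, samples, alpha = alpha, fc_threshold = fc)
  emit(calls, "calls.tsv")

  strains <- unique(samples$strain)
  bias <- do.call(rbind, lapply(strains, function(s) {
    tryCatch(direction_bias_test(calls, s),
             error = function(e) data.frame(strain = s, n_up = 0, n_down = 0,
                                            chisq = NA, p = NA))
  }))
  emit(bias, "direction_counts.tsv")

  part <- partition_calls(calls, strains)
  part_df <- data.frame(
    transcript = rownames(part$directions),
    region = apply(!is.na(part$directions), 1,
                   function(m) paste(strains[m], collapse = ":")),
    part$directions,
    check.names = FALSE, stringsAsFactors = FALSE
  )
  emit(part_df, "partition.tsv")

  combos <- c(utils::combn(strains, 2, simplify = FALSE),
              if (length(strains) >= 3) utils::combn(strains, 3, simplify = FALSE))
  conc <- do.call(rbind, lapply(combos, function(cc) {
    s <- concordance(part, cc)
    data.frame(strains = paste(cc, collapse = ":"),
               n_overlapping = s$n_overlapping,
               n_same_direction = s$n_same_direction,
               n_up = length(s$up), n_down = length(s$down),
               stringsAsFactors = FALSE)
  }))
  emit(conc, "concordance.tsv")

  nwk_path <- file.path(out_dir, "dendrogram.nwk")
  cl <- tryCatch(cluster_overlap(mat, samples, part), error = function(e) NULL)
  writeLines(if (is.null(cl)) "" else cl$newick, nwk_path)
  files <- c(files, "dendrogram.nwk")

  pheno <- pool_groups(pheno)
  pheno <- body_weight_change(pheno)
  measures <- c("bw_change", "adrenal_mg", "thymus_mg", "heart_mg",
                "brain_g", "plasma_cort")
  anova_rows <- do.call(rbind, lapply(intersect(measures, names(pheno)), function(m) {
    vals <- pheno[[m]]
    grp <- paste(pheno$strain, pheno$pooled_group)
    keep <- if (m == "plasma_cort") {
      remove_outliers(vals, grp, k = config$outlier_k %||% 2)$kept
    } else rep(TRUE, length(vals))
    res <- anova2_type3(vals[keep], pheno$strain[keep],
                        pheno$pooled_group[keep],
                        names_ab = c("strain", "treatment"))
    cbind(measure = m, res)
  }))
  emit(anova_rows, "phenotype_anova.tsv")

  fc_res <- fcort_analysis(fcort)
  emit(fc_res, "fcort_anova.tsv")

  background <- rownames(mat)
  target <- unique(calls$transcript[calls$passes])
  enr <- if (length(target) > 0) {
    ora(target, background, sets, min_size = min_cat, alpha = alpha)
  } else {
    data.frame(category = character(), set_size = integer(),
               overlap = integer(), p = numeric(), q = numeric(),
               significant = logical())
  }
  emit(enr, "enrichment.tsv")

  manifest <- list(
    package = "stresspatterns",
    version = as.character(utils::packageVersion("stresspatterns")),
    seed = seed,
    thresholds = list(alpha = alpha, fc = fc,
                      outlier_k = config$outlier_k %||% 2,
                      min_category = min_cat),
    simulate = isTRUE(config$simulate),
    files = files,
    complete = length(files) == 8
  )
  write_config(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
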