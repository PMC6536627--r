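#' Read a GMT gene-set collection
#'
#' Standard tab-delimited GMT: set name, description, then member ids.
#'
#' @param path GMT file path.
#' @return Named list of character vectors of member ids.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(parts, length, integer(1)) < 3)
  if (length(short) > 0) {
    stop("GMT line(s) with fewer than 3 fields: ", paste(short, collapse = ", "))
  }
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, character(1), 1)
  if (anyDuplicated(names(sets))) stop("duplicate set names in GMT")
  sets
}

#' Write a GMT gene-set collection
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param descriptions optional description field per set (default "na").
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- mapply(function(nm, desc, ids) {
    paste(c(nm, desc, ids), collapse = "\t")
  }, names(sets), descriptions, sets)
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric over-representation analysis
#'
#' For each gene set (restricted to the background universe), tests
#' whether the target list overlaps the set more than expected when
#' drawing |target| ids from the background without replacement: the
#' upper-tail hypergeometric probability of observing at least the seen
#' overlap. Categories smaller than `min_size` within the background are
#' excluded before testing, and BH adjustment runs over the tested
#' categories only. A category is flagged significant when its adjusted
#' p-value is below `alpha`.
#'
#' @param target character vector of ids, a subset of `background`.
#' @param background character vector: the analysis universe.
#' @param sets named list of id vectors (e.g. from [read_gmt()]).
#' @param min_size minimum in-background category size (default 5).
#' @param alpha significance level on the BH-adjusted p (default 0.05).
#' @return data.frame sorted by p: `category`, `set_size`, `overlap`,
#'   `p`, `q`, `significant`.
#' @export
ora <- function(target, background, sets, min_size = 5, alpha = 0.05) {
  target <- unique(target)
  background <- unique(background)
  stray <- setdiff(target, background)
  if (length(stray) > 0) {
    stop("target ids not in background: ",
         paste(utils::head(stray, 10), collapse = ", "))
  }
  if (any(vapply(sets, length, integer(1)) == 0)) stop("empty gene set")
  N <- length(background)
  n <- length(target)
  restricted <- lapply(sets, intersect, background)
  m <- vapply(restricted, length, integer(1))
  tested <- names(restricted)[m >= min_size]
  if (length(tested) == 0) {
    return(data.frame(category = character(), set_size = integer(),
                      overlap = integer(), p = numeric(), q = numeric(),
                      significant = logical(), stringsAsFactors = FALSE))
  }
  k <- vapply(restricted[tested], function(s) length(intersect(s, target)),
              integer(1))
  p <- stats::phyper(k - 1, m[tested], N - m[tested], n, lower.tail = FALSE)
  q <- bh_adjust(p)
  out <- data.frame(
    category = tested,
    set_size = m[tested],
    overlap = k,
    p = p,
    q = q,
    significant = q < alpha,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  out[order(out$p, out$category), , drop = FALSE]
}
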