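#' Partition passing calls into exclusive Venn regions
#'
#' Each transcript passing in at least one strain is assigned to exactly
#' one region named by the strains it passes in, joined by ":" in the
#' supplied strain order (e.g. "B", "B:N", "B:N:D"). Pairwise regions are
#' exclusive of the triple region; the union of all regions is the set of
#' transcripts passing anywhere.
#'
#' @param calls data.frame from [call_stress_transcripts()] (rows with
#'   `passes = TRUE` are used; duplicated transcript-strain pairs among
#'   them are an error).
#' @param strains strain order used for region labels; defaults to the
#'   order of appearance in `calls`.
#' @return Object of class `overlap_partition`: list with `regions` (named
#'   list of transcript-id vectors, sorted), `directions` (data.frame
#'   transcript x strain of called directions, NA where not passing) and
#'   `strains`.
#' @export
partition_calls <- function(calls, strains = unique(calls$strain)) {
  pass <- calls[calls$passes, , drop = FALSE]
  if (anyDuplicated(pass[, c("transcript", "strain")])) {
    stop("duplicate (transcript, strain) calls")
  }
  pass <- pass[order(pass$transcript), , drop = FALSE]
  ids <- sort(unique(pass$transcript))
  dir <- matrix(NA_character_, nrow = length(ids), ncol = length(strains),
                dimnames = list(ids, strains))
  dir[cbind(match(pass$transcript, ids), match(pass$strain, strains))] <- pass$direction
  member <- !is.na(dir)
  region_of <- apply(member, 1, function(m) paste(strains[m], collapse = ":"))
  region_names <- unlist(lapply(seq_along(strains), function(k) {
    utils::combn(strains, k, paste, collapse = ":")
  }))
  regions <- lapply(region_names, function(r) ids[region_of == r])
  names(regions) <- region_names
  structure(
    list(regions = regions,
         directions = as.data.frame(dir, stringsAsFactors = FALSE),
         strains = strains),
    class = "overlap_partition"
  )
}

#' @export
print.overlap_partition <- function(x, ...) {
  sizes <- vapply(x$regions, length, integer(1))
  cat("Overlap partition over strains:", paste(x$strains, collapse = ", "), "\n")
  print(sizes)
  multi <- sizes[vapply(strsplit(names(sizes), ":"), length, integer(1)) >= 2]
  cat("union:", sum(sizes), "  multi-strain:", sum(multi), "\n")
  invisible(x)
}

#' Region sizes of an overlap partition
#'
#' @param partition an `overlap_partition`.
#' @return Named integer vector of exclusive region sizes.
#' @export
region_sizes <- function(partition) {
  vapply(partition$regions, length, integer(1))
}

#' Direction concordance within a strain overlap
#'
#' For the transcripts passing in all requested strains (inclusive
#' overlap: membership in further strains is ignored), counts how many
#' are called in the same direction in every requested strain.
#'
#' @param partition an `overlap_partition` from [partition_calls()].
#' @param strains two or three strain labels.
#' @return List of class `concordance_summary`: `strains`,
#'   `n_overlapping`, `n_same_direction`, and member id lists `up`,
#'   `down` (concordant by direction) and `discordant`.
#' @export
concordance <- function(partition, strains) {
  unknown <- setdiff(strains, partition$strains)
  if (length(unknown) > 0) {
    stop("unknown strain label(s): ", paste(unknown, collapse = ", "))
  }
  if (length(strains) < 2) stop("concordance needs >= 2 strains")
  dir <- partition$directions[, strains, drop = FALSE]
  in_all <- rowSums(!is.na(dir)) == length(strains)
  dir <- dir[in_all, , drop = FALSE]
  same <- apply(dir, 1, function(d) all(d == d[1]))
  ids <- rownames(dir)
  structure(
    list(strains = strains,
         n_overlapping = nrow(dir),
         n_same_direction = sum(same),
         up = ids[same & dir[, 1] == "UP"],
         down = ids[same & dir[, 1] == "DOWN"],
         discordant = ids[!same]),
    class = "concordance_summary"
  )
}

#' @export
print.concordance_summary <- function(x, ...) {
  cat(paste(x$strains, collapse = " & "), ": ",
      x$n_same_direction, " of ", x$n_overlapping,
      " overlapping transcripts concordant (",
      length(x$up), " up, ", length(x$down), " down)\n", sep = "")
  invisible(x)
}

#' Hierarchically cluster shared stress-responsive transcripts
#'
#' Transcripts passing in two or more strains are clustered on their
#' per-strain signed log2 contrasts (mean CMS-R minus mean NH-R, one
#' value per strain), using average-linkage agglomeration on Euclidean
#' distances. Rows are pre-sorted by transcript id so the leaf order is
#' deterministic.
#'
#' @param mat transcripts x samples log2 matrix.
#' @param samples sample table.
#' @param partition an `overlap_partition`.
#' @return List: `hclust` (the tree), `leaf_order` (transcript ids in
#'   dendrogram order), `features` (the contrast matrix), `newick`
#'   (Newick string with merge heights as branch lengths).
#' @export
cluster_overlap <- function(mat, samples, partition) {
  n_str <- vapply(strsplit(names(partition$regions), ":"), length, integer(1))
  ids <- sort(unique(unlist(partition$regions[n_str >= 2], use.names = FALSE)))
  if (length(ids) < 2) stop("need >= 2 multi-strain transcripts to cluster")
  missing <- setdiff(ids, rownames(mat))
  if (length(missing) > 0) {
    stop("multi-strain transcripts absent from matrix: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  feats <- vapply(partition$strains, function(st) {
    nhr <- samples$sample_id[samples$strain == st & samples$treatment == "NH-R"]
    cmsr <- samples$sample_id[samples$strain == st & samples$treatment == "CMS-R"]
    if (length(nhr) == 0 || length(cmsr) == 0) {
      stop("strain '", st, "' is missing NH-R or CMS-R samples for the contrast")
    }
    rowMeans(mat[ids, cmsr, drop = FALSE]) - rowMeans(mat[ids, nhr, drop = FALSE])
  }, numeric(length(ids)))
  feats <- matrix(feats, nrow = length(ids),
                  dimnames = list(ids, partition$strains))
  hc <- stats::hclust(stats::dist(feats, method = "euclidean"),
                      method = "average")
  phy <- ape::as.phylo(hc)
  list(hclust = hc,
       leaf_order = hc$labels[hc$order],
       features = feats,
       newick = ape::write.tree(phy))
}
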