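#' Construct a subclonal reconstruction
#'
#' The common representation for outputs of ITH methods and for simulated
#' ground truth: a set of clones, each with a cellular prevalence (CCF) and a
#' disjoint set of member mutations.
#'
#' @param clone_ids Character vector of clone labels (unique).
#' @param ccfs Numeric vector of cellular prevalences in (0, 1], one per clone.
#' @param assignment Named character vector mapping `mutation_id` (names) to
#'   `clone_id` (values); every mutation belongs to exactly one clone.
#' @param purity Optional sample purity.
#'
#' @return Object of class `"subclonal_recon"`: list with `clones`
#'   (`data.frame` of `clone_id`, `ccf`, `n_mut`), `assignment`, `purity`.
#' @export
subclonal_reconstruction <- function(clone_ids, ccfs, assignment,
                                     purity = NA_real_) {
  clone_ids <- as.character(clone_ids)
  if (anyDuplicated(clone_ids)) stop("duplicate clone ids")
  if (length(ccfs) != length(clone_ids)) {
    stop("ccfs and clone_ids lengths differ")
  }
  if (any(!is.na(ccfs) & (ccfs <= 0 | ccfs > 1))) {
    stop("clone prevalences must be in (0, 1]")
  }
  if (length(clone_ids) < 1L) stop("reconstruction needs at least one clone")
  if (is.null(names(assignment)) || anyDuplicated(names(assignment))) {
    stop("assignment must be named by unique mutation ids")
  }
  bad <- setdiff(unique(assignment), clone_ids)
  if (length(bad)) stop("assignment references unknown clone(s): ",
                        paste(bad, collapse = ", "))
  n_mut <- as.integer(table(factor(assignment, levels = clone_ids)))
  structure(list(
    clones = data.frame(clone_id = clone_ids, ccf = as.numeric(ccfs),
                        n_mut = n_mut, stringsAsFactors = FALSE),
    assignment = assignment,
    purity = purity
  ), class = "subclonal_recon")
}

#' @export
print.subclonal_recon <- function(x, ...) {
  cat(sprintf("Subclonal reconstruction: %d clone(s), %d mutation(s)\n",
              nrow(x$clones), length(x$assignment)))
  print(x$clones, row.names = FALSE)
  invisible(x)
}

#' Number of clones in a reconstruction
#' @param recon A `"subclonal_recon"`.
#' @return Integer clone count J.
#' @export
n_clones <- function(recon) {
  stopifnot(inherits(recon, "subclonal_recon"))
  nrow(recon$clones)
}

#' Convert a simulated clone structure to a reconstruction
#'
#' @param structure A `"clone_structure"` ground truth.
#' @param purity Optional purity to attach.
#' @return A `"subclonal_recon"`.
#' @export
as_reconstruction <- function(structure, purity = NA_real_) {
  stopifnot(inherits(structure, "clone_structure"))
  subclonal_reconstruction(structure$clone_ids, structure$ccfs,
                           structure$assignment, purity = purity)
}

#' Post-filter clones by minimum mutation count
#'
#' Keeps clones with at least `min_snvs` member mutations, dropping the
#' mutations of removed clones — except when no clone reaches `min_snvs`, in
#' which case all clones are kept unchanged.
#'
#' @param recon A `"subclonal_recon"`.
#' @param min_snvs Minimum mutations per retained clone (default 5).
#' @return The filtered `"subclonal_recon"`.
#' @export
postfilter_clones <- function(recon, min_snvs = 5L) {
  stopifnot(inherits(recon, "subclonal_recon"))
  if (nrow(recon$clones) == 0L) stop("empty reconstruction")
  keep <- recon$clones$n_mut >= min_snvs
  if (!any(keep)) return(recon)
  kept_ids <- recon$clones$clone_id[keep]
  assignment <- recon$assignment[recon$assignment %in% kept_ids]
  subclonal_reconstruction(kept_ids, recon$clones$ccf[keep], assignment,
                           purity = recon$purity)
}

#' Baseline subclonal reconstruction by CCF-grid binning
#'
#' A deliberately simple reference reconstructor: CCF (or VAF) values are
#' assigned to the nearest point of a fixed grid with spacing `grid_width`;
#' occupied bins with fewer than `min_snvs` members are merged into the
#' nearest heavier bin (ties broken toward the heavier neighbour) until none
#' remain, unless only one bin is left. Each final bin is a clone whose
#' prevalence is the mutation-weighted mean of its member values.
#'
#' @param values Numeric vector of per-mutation CCFs (or VAFs) in (0, 1];
#'   names, if present, become mutation ids.
#' @param grid_width Bin width of the CCF grid (default 0.1).
#' @param min_snvs Minimum bin occupancy before merging (default 5).
#' @return A `"subclonal_recon"`.
#' @export
baseline_reconstruct <- function(values, grid_width = 0.1, min_snvs = 5L) {
  if (length(values) == 0L) stop("no values to reconstruct from")
  if (is.null(names(values))) {
    names(values) <- sprintf("mut%05d", seq_along(values))
  }
  v <- pmin(pmax(values, 1e-6), 1)
  bin <- round(v / grid_width)  # nearest grid point k * grid_width
  groups <- split(names(v), bin)
  centers <- vapply(groups, function(ids) mean(v[ids]), numeric(1))
  sizes <- lengths(groups)
  while (length(groups) > 1L && any(sizes < min_snvs)) {
    small <- which(sizes < min_snvs)
    src <- small[which.min(sizes[small])]
    others <- setdiff(seq_along(groups), src)
    d <- abs(centers[others] - centers[src])
    cand <- others[d == min(d)]
    dst <- cand[which.max(sizes[cand])]  # tie -> heavier bin
    groups[[dst]] <- c(groups[[dst]], groups[[src]])
    centers[dst] <- mean(v[groups[[dst]]])
    sizes[dst] <- sizes[dst] + sizes[src]
    groups <- groups[-src]; centers <- centers[-src]; sizes <- sizes[-src]
  }
  ord <- order(centers, decreasing = TRUE)
  groups <- groups[ord]; centers <- centers[ord]
  clone_ids <- sprintf("b%02d", seq_along(groups))
  assignment <- rep(clone_ids, times = lengths(groups))
  names(assignment) <- unlist(groups, use.names = FALSE)
  subclonal_reconstruction(clone_ids, unname(centers), assignment)
}

#' Load a reconstruction from assignment and clone tables
#'
#' @param assignment A `data.frame` with columns `mutation_id`, `clone_id`,
#'   or a path to such a TSV.
#' @param clones A `data.frame` with columns `clone_id`, `ccf` (and
#'   optionally `n_mut`, ignored and recomputed), or a path to such a TSV.
#' @param purity Optional purity.
#' @return A validated `"subclonal_recon"`.
#' @export
load_reconstruction <- function(assignment, clones, purity = NA_real_) {
  if (is.character(assignment)) {
    assignment <- utils::read.table(assignment, header = TRUE, sep = "\t",
                                    stringsAsFactors = FALSE,
                                    colClasses = "character")
  }
  if (is.character(clones)) {
    clones <- utils::read.table(clones, header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE)
  }
  stopifnot(all(c("mutation_id", "clone_id") %in% names(assignment)),
            all(c("clone_id", "ccf") %in% names(clones)))
  if (anyDuplicated(assignment$mutation_id)) {
    stop("duplicate mutation assignment")
  }
  a <- as.character(assignment$clone_id)
  names(a) <- assignment$mutation_id
  subclonal_reconstruction(clones$clone_id, as.numeric(clones$ccf), a,
                           purity = purity)
}

#' Write a reconstruction as assignment/clone TSVs
#'
#' @param recon A `"subclonal_recon"`.
#' @param assignment_path,clones_path Output TSV paths.
#' @return Invisibly, the two paths.
#' @export
write_reconstruction <- function(recon, assignment_path, clones_path) {
  stopifnot(inherits(recon, "subclonal_recon"))
  utils::write.table(
    data.frame(mutation_id = names(recon$assignment),
               clone_id = unname(recon$assignment)),
    assignment_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(recon$clones, clones_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(assignment_path, clones_path))
}
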