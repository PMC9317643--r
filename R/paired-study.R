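#' Paired-biospecimen study container
#'
#' Holds two aligned metabolite x subject abundance matrices (biospecimens A
#' and B), the per-subject group labels, and optional generating truth. Both
#' matrices must share dimensions, row (metabolite) names and column
#' (subject) names; raw-scale values must be strictly positive at observed
#' cells so the log-transform is invertible.
#'
#' @param A,B metabolite x subject matrices (may contain `NA` for missing).
#' @param groups two-level factor of length `ncol(A)`.
#' @param true_r optional per-metabolite generating correlation.
#' @param true_de optional per-metabolite logical differential flag.
#' @param log_scale logical; `FALSE` for raw abundances, `TRUE` after
#'   [log_transform_study()].
#' @return an object of class `paired_study`.
#' @export
paired_study <- function(A, B, groups, true_r = NULL, true_de = NULL,
                         log_scale = FALSE) {
  stopifnot(is.matrix(A), is.matrix(B))
  if (!all(dim(A) == dim(B)))
    stop_param("biospecimen matrices must share dimensions")
  if (!identical(rownames(A), rownames(B)) ||
      !identical(colnames(A), colnames(B)))
    stop_param("biospecimen matrices must share metabolite and subject names")
  groups <- as.factor(groups)
  if (length(groups) != ncol(A))
    stop_param("'groups' must have one label per subject (column)")
  if (nlevels(droplevels(groups)) != 2)
    stop_param("'groups' must have exactly two levels")
  if (!log_scale && (any(A <= 0, na.rm = TRUE) || any(B <= 0, na.rm = TRUE)))
    stop_param("raw abundances must be strictly positive")
  if (!is.null(true_r)) stopifnot(length(true_r) == nrow(A))
  if (!is.null(true_de)) stopifnot(length(true_de) == nrow(A))
  structure(
    list(A = A, B = B, groups = droplevels(groups),
         true_r = true_r, true_de = true_de, log_scale = log_scale),
    class = "paired_study")
}

#' @export
print.paired_study <- function(x, ...) {
  cat(sprintf("paired_study: %d metabolites x %d subjects (%s scale)\n",
              nrow(x$A), ncol(x$A), if (x$log_scale) "log" else "raw"))
  cat(sprintf("  groups: %s\n",
              paste(sprintf("%s=%d", levels(x$groups), table(x$groups)),
                    collapse = ", ")))
  na_a <- sum(is.na(x$A)); na_b <- sum(is.na(x$B))
  cat(sprintf("  missing cells: A=%d, B=%d\n", na_a, na_b))
  if (!is.null(x$true_de))
    cat(sprintf("  true differential metabolites: %d\n", sum(x$true_de)))
  invisible(x)
}

#' @export
dim.paired_study <- function(x) dim(x$A)

#' Natural-log transform a paired study
#'
#' Applies `log()` to every observed cell of both biospecimen matrices,
#' preserving missing cells. Errors if any observed value is non-positive
#' (the transform must be invertible).
#'
#' @param study a raw-scale [paired_study].
#' @return the study on the log scale.
#' @export
log_transform_study <- function(study) {
  stopifnot(inherits(study, "paired_study"))
  if (study$log_scale) stop_param("study is already on the log scale")
  study$A <- log_transform(study$A)
  study$B <- log_transform(study$B)
  study$log_scale <- TRUE
  study
}

#' Apply missingness masks to a paired study
#'
#' @param study a complete [paired_study].
#' @param mask_A,mask_B logical matrices from [induce_missingness()]
#'   (`TRUE` = missing); either may be `NULL` for no missingness.
#' @return the study with masked cells set to `NA`.
#' @export
mask_study <- function(study, mask_A = NULL, mask_B = NULL) {
  stopifnot(inherits(study, "paired_study"))
  if (!is.null(mask_A)) study$A <- apply_mask(study$A, mask_A)
  if (!is.null(mask_B)) study$B <- apply_mask(study$B, mask_B)
  study
}

#' Write a paired study to TSV files
#'
#' Writes each biospecimen matrix as a TSV (rows = metabolites, columns =
#' subjects, `NA` for missing cells) plus a companion TSV holding subject
#' group labels and, when present, the per-metabolite truth annotations
#' (`true_r`, `true_de`).
#'
#' @param study a [paired_study].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return invisibly, the paths written.
#' @export
write_paired_study <- function(study, dir, prefix = "study") {
  stopifnot(inherits(study, "paired_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(prefix, c("_biospecimenA.tsv",
                                           "_biospecimenB.tsv",
                                           "_subjects.tsv",
                                           "_metabolites.tsv")))
  write_matrix_tsv(study$A, paths[1])
  write_matrix_tsv(study$B, paths[2])
  utils::write.table(
    data.frame(subject = colnames(study$A), group = study$groups),
    paths[3], sep = "\t", quote = FALSE, row.names = FALSE)
  met <- data.frame(metabolite = rownames(study$A))
  if (!is.null(study$true_r)) met$true_r <- study$true_r
  if (!is.null(study$true_de)) met$true_de <- study$true_de
  utils::write.table(met, paths[4], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

#' Read a paired study from delimited text
#'
#' Counterpart of [write_paired_study()]; also the entry point for
#' user-supplied data: two metabolite x subject TSVs plus a group-label TSV
#' with columns `subject` and `group`.
#'
#' @param path_A,path_B biospecimen matrix TSVs (first column = metabolite
#'   IDs).
#' @param path_groups subject/group TSV.
#' @param log_scale whether the matrices are already log-transformed.
#' @return a [paired_study].
#' @export
read_paired_study <- function(path_A, path_B, path_groups,
                              log_scale = FALSE) {
  A <- read_matrix_tsv(path_A)
  B <- read_matrix_tsv(path_B)
  gr <- utils::read.delim(path_groups, stringsAsFactors = FALSE)
  if (!all(c("subject", "group") %in% names(gr)))
    stop_param("group file needs 'subject' and 'group' columns")
  idx <- match(colnames(A), gr$subject)
  if (anyNA(idx)) stop_param("group file is missing some subjects")
  paired_study(A, B, factor(gr$group[idx]), log_scale = log_scale)
}

write_matrix_tsv <- function(x, path) {
  df <- data.frame(metabolite = rownames(x), x, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}
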