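#' Steady-state expression dataset
#'
#' Container for a steady-state expression matrix (experiments x genes) in
#' Boolean and/or real-valued form, with per-experiment annotations:
#' `id` (experiment identifier), `MG` (mutated gene; `NA` for wild type),
#' `ET` (experiment type: `"WT"`, `"KO"` or `"OE"`) and `WT` (id of the base
#' wild-type experiment; `NA` for wild-type rows).
#'
#' @param genes character vector of gene names (column order fixes indices).
#' @param annotations data frame with columns `id`, `MG`, `ET`, `WT`.
#' @param bool optional integer 0/1 matrix, experiments x genes.
#' @param real optional numeric matrix, experiments x genes.
#' @return An object of class `expression_dataset`.
#' @export
expression_dataset <- function(genes, annotations, bool = NULL, real = NULL) {
  genes <- as.character(genes)
  ann <- as.data.frame(annotations, stringsAsFactors = FALSE)
  need <- c("id", "MG", "ET", "WT")
  if (!all(need %in% names(ann)))
    stop("annotations need columns id, MG, ET, WT")
  ann <- ann[need]
  for (cc in need) ann[[cc]] <- as.character(ann[[cc]])
  ann$MG[!is.na(ann$MG) & ann$MG == ""] <- NA_character_
  ann$WT[!is.na(ann$WT) & ann$WT == ""] <- NA_character_
  R <- nrow(ann)
  if (anyDuplicated(genes)) stop("gene names must be unique")
  if (anyDuplicated(ann$id)) stop("duplicate experiment ids")
  bad <- which(!ann$ET %in% c("WT", "KO", "OE"))
  if (length(bad))
    stop("unknown experiment type '", ann$ET[bad[1]], "' in row ", bad[1])
  pert <- ann$ET != "WT"
  if (any(pert & is.na(ann$MG)))
    stop("perturbation rows must name a mutated gene (MG)")
  if (any(!pert & !is.na(ann$MG)))
    stop("wild-type rows must not name a mutated gene")
  if (any(!ann$MG[pert] %in% genes))
    stop("MG names an unknown gene: ",
         ann$MG[pert][!ann$MG[pert] %in% genes][1])
  wt_ids <- ann$id[!pert]
  dangling <- pert & (is.na(ann$WT) | !ann$WT %in% wt_ids)
  if (any(dangling))
    stop("row '", ann$id[which(dangling)[1]],
         "' references a missing base wild-type experiment")
  check_mat <- function(m, what, integer_bits) {
    if (is.null(m)) return(NULL)
    m <- as.matrix(m)
    if (nrow(m) != R || ncol(m) != length(genes))
      stop(what, " matrix must be ", R, " experiments x ", length(genes), " genes")
    if (anyNA(m)) stop("missing values in ", what, " matrix")
    if (integer_bits) {
      if (!all(m %in% 0:1)) stop("Boolean matrix must contain only 0/1")
      m <- matrix(as.integer(m), nrow = R)
    }
    dimnames(m) <- list(ann$id, genes)
    m
  }
  structure(list(genes = genes, annotations = ann,
                 bool = check_mat(bool, "Boolean", TRUE),
                 real = check_mat(real, "real", FALSE)),
            class = "expression_dataset")
}

n_experiments <- function(dataset) nrow(dataset$annotations)

# Resolve each row's base wild-type row index (a WT row is its own base).
base_wt_index <- function(dataset) {
  ann <- dataset$annotations
  idx <- match(ann$WT, ann$id)
  is_wt <- ann$ET == "WT"
  idx[is_wt] <- which(is_wt)
  idx
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat("Expression dataset:", n_experiments(x), "experiments x",
      length(x$genes), "genes (",
      sum(x$annotations$ET == "WT"), "WT,",
      sum(x$annotations$ET == "KO"), "KO,",
      sum(x$annotations$ET == "OE"), "OE )\n")
  cat(" matrices:", paste(c("boolean", "real")[!c(is.null(x$bool), is.null(x$real))],
                          collapse = ", "), "\n")
  invisible(x)
}
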