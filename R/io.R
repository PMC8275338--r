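#' Read a steady-state expression dataset from TSV
#'
#' The file is tab-separated with a header. The first columns are `id`
#' (optional), `MG`, `ET`, `WT`; the remaining header fields name the genes
#' (their order defines gene indices). Empty annotation fields are written
#' as `-`. When the `id` column is absent, experiment ids are
#' auto-generated as `WT01`, `KO01`, ... in row order per type.
#'
#' @param path file path.
#' @param mode `"boolean"` (0/1 values) or `"real"` (numeric values).
#' @return An [expression_dataset()].
#' @export
read_dataset <- function(path, mode = c("boolean", "real")) {
  mode <- match.arg(mode)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2) stop("dataset file needs a header and at least one row")
  cells <- strsplit(lines, "\t", fixed = TRUE)
  header <- cells[[1]]
  has_id <- header[1] == "id"
  meta_cols <- if (has_id) 4L else 3L
  expect <- if (has_id) c("id", "MG", "ET", "WT") else c("MG", "ET", "WT")
  if (!identical(header[seq_len(meta_cols)], expect))
    stop("header must start with ", paste(expect, collapse = ", "))
  genes <- header[-seq_len(meta_cols)]
  if (!length(genes)) stop("no gene columns in header")
  n <- length(cells) - 1L
  blank <- function(x) ifelse(x %in% c("-", ""), NA_character_, x)
  ann <- data.frame(id = character(n), MG = character(n), ET = character(n),
                    WT = character(n), stringsAsFactors = FALSE)
  vals <- matrix(NA_real_, n, length(genes))
  for (r in seq_len(n)) {
    row <- cells[[r + 1L]]
    if (length(row) != length(header))
      stop("line ", r + 1L, ": expected ", length(header), " fields, found ",
           length(row))
    off <- if (has_id) 1L else 0L
    ann$id[r] <- if (has_id) row[1] else NA_character_
    ann$MG[r] <- blank(row[off + 1L])
    ann$ET[r] <- row[off + 2L]
    ann$WT[r] <- blank(row[off + 3L])
    if (!ann$ET[r] %in% c("WT", "KO", "OE"))
      stop("line ", r + 1L, ": unknown experiment type '", ann$ET[r], "'")
    v <- suppressWarnings(as.numeric(row[-seq_len(meta_cols)]))
    if (anyNA(v)) stop("line ", r + 1L, ": non-numeric expression value")
    vals[r, ] <- v
  }
  if (!has_id) {
    counts <- c(WT = 0L, KO = 0L, OE = 0L)
    for (r in seq_len(n)) {
      counts[ann$ET[r]] <- counts[ann$ET[r]] + 1L
      ann$id[r] <- sprintf("%s%02d", ann$ET[r], counts[ann$ET[r]])
    }
  }
  if (mode == "boolean") {
    if (!all(vals %in% c(0, 1))) stop("boolean mode requires 0/1 values")
    expression_dataset(genes, ann, bool = vals)
  } else {
    expression_dataset(genes, ann, real = vals)
  }
}

#' Write a dataset to TSV
#'
#' @param dataset an [expression_dataset()].
#' @param path output file.
#' @param mode which matrix to write.
#' @export
write_dataset <- function(dataset, path, mode = c("boolean", "real")) {
  mode <- match.arg(mode)
  m <- if (mode == "boolean") dataset$bool else dataset$real
  if (is.null(m)) stop("dataset carries no ", mode, " matrix")
  ann <- dataset$annotations
  fmt <- function(x) ifelse(is.na(x), "-", x)
  body <- vapply(seq_len(nrow(ann)), function(r) {
    vals <- if (mode == "boolean") as.character(m[r, ])
            else sprintf("%.10g", m[r, ])
    paste(c(ann$id[r], fmt(ann$MG[r]), ann$ET[r], fmt(ann$WT[r]), vals),
          collapse = "\t")
  }, character(1))
  writeLines(c(paste(c("id", "MG", "ET", "WT", dataset$genes), collapse = "\t"),
               body), path)
  invisible(path)
}

#' Write a network as rule text and/or a signed edge list
#'
#' The rule format is one rule per line,
#' `gene = (regulator,I,O)(regulator,I,O)...:Odef`; the SIF-like edge list
#' is `source TAB +1|-1 TAB target`.
#'
#' @param net a [boolean_network()].
#' @param rule_path,sif_path output paths (`NULL` skips).
#' @export
write_network <- function(net, rule_path = NULL, sif_path = NULL) {
  stopifnot(inherits(net, "boolean_network"))
  if (!is.null(rule_path)) {
    lines <- vapply(net$rules, function(r) {
      tup <- paste0("(", net$genes[r$regulators], ",", r$I, ",", r$O, ")",
                    collapse = "")
      paste0(net$genes[r$target], " = ", tup, ":", r$default_out)
    }, character(1))
    writeLines(lines, rule_path)
  }
  if (!is.null(sif_path)) {
    e <- network_edges(net)
    writeLines(sprintf("%s\t%+d\t%s", e$from_gene, e$sign, e$to_gene), sif_path)
  }
  invisible(net)
}

#' Read a network from rule text
#'
#' Gene order in the file defines gene indices. In strict mode a default
#' output differing from the complement of the last canalyzed value is an
#' error; in permissive mode it is kept with a warning (foreign rule files).
#'
#' @param path rule file.
#' @param strict enforce the default-output convention.
#' @return A [boolean_network()].
#' @export
read_network <- function(path, strict = TRUE) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- regmatches(lines, regexec("^\\s*(\\S+)\\s*=\\s*(.*?):([01])\\s*$", lines))
  bad <- which(vapply(parts, length, integer(1)) != 4)
  if (length(bad)) stop("line ", bad[1], ": malformed rule syntax")
  genes <- vapply(parts, `[[`, character(1), 2)
  if (anyDuplicated(genes))
    stop("two rules assigned to gene '", genes[duplicated(genes)][1], "'")
  rules <- vector("list", length(genes))
  for (i in seq_along(parts)) {
    body <- parts[[i]][3]
    tups <- regmatches(body,
                       gregexpr("\\(\\s*([^,()\\s]+)\\s*,\\s*([01])\\s*,\\s*([01])\\s*\\)",
                                body))[[1]]
    if (!length(tups) ||
        nchar(gsub("\\s", "", paste(tups, collapse = ""))) != nchar(gsub("\\s", "", body)))
      stop("line ", i, ": malformed tuple syntax in rule of '", genes[i], "'")
    fields <- regmatches(tups, regexec("\\(\\s*([^,()\\s]+)\\s*,\\s*([01])\\s*,\\s*([01])\\s*\\)", tups))
    regs <- vapply(fields, `[[`, character(1), 2)
    idx <- match(regs, genes)
    if (anyNA(idx))
      stop("line ", i, ": unknown regulator '", regs[is.na(idx)][1], "'")
    rules[[i]] <- ncf_rule(i, idx,
                           as.integer(vapply(fields, `[[`, character(1), 3)),
                           as.integer(vapply(fields, `[[`, character(1), 4)),
                           default_out = as.integer(parts[[i]][4]),
                           permissive = !strict)
  }
  boolean_network(genes, rules)
}

#' Write / read a constraint set
#'
#' TSV with header `source`, `target`, `sign`, `directness`; genes are
#' written by name.
#'
#' @param constraints a `constraint_set` (carrying its gene names).
#' @param path file path.
#' @export
write_constraints <- function(constraints, path) {
  genes <- attr(constraints, "genes")
  df <- data.frame(source = genes[constraints$source],
                   target = genes[constraints$target],
                   sign = sprintf("%+d", constraints$sign),
                   directness = constraints$directness)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_constraints
#' @param genes gene name vector defining indices.
#' @export
read_constraints <- function(path, genes) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("source", "target", "sign", "directness")
  if (!all(need %in% names(df))) stop("constraint file needs columns ",
                                      paste(need, collapse = ", "))
  src <- match(df$source, genes); tgt <- match(df$target, genes)
  if (anyNA(src) || anyNA(tgt)) stop("constraint references an unknown gene")
  if (!all(df$directness %in% c("direct", "indirect")))
    stop("directness must be 'direct' or 'indirect'")
  sg <- as.integer(df$sign)
  if (!all(sg %in% c(-1L, 1L))) stop("sign must be +1 or -1")
  new_constraint_set(data.frame(source = src, target = tgt, sign = sg,
                                directness = df$directness,
                                stringsAsFactors = FALSE), genes)
}

report_pairs <- function(report) {
  if (inherits(report, "structural_report")) {
    p <- report[c("tp", "fp", "fn", "tn", "precision", "recall",
                  "structural_accuracy")]
    setNames(as.numeric(p), names(p))
  } else if (inherits(report, "dynamics_report")) {
    c(dynamics_accuracy = report$dynamics_accuracy,
      n_experiments = length(report$per_experiment),
      n_truncated = sum(report$truncated),
      setNames(report$per_gene, paste0("s_bar.", names(report$per_gene))))
  } else stop("unsupported report type")
}

#' Serialize a scoring report
#'
#' Writes a structural or dynamics report as flat key-value TSV or JSON
#' (chosen by file extension: `.json` for JSON, anything else TSV). The
#' per-gene average similarities of a dynamics report are included under
#' `s_bar.<gene>` keys.
#'
#' @param report a `structural_report` or `dynamics_report`.
#' @param path output path.
#' @export
write_report <- function(report, path) {
  kv <- report_pairs(report)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(as.list(kv), path, auto_unbox = TRUE, digits = NA)
  } else {
    writeLines(sprintf("%s\t%.10g", names(kv), kv), path)
  }
  invisible(path)
}
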