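#' Read a Ct table from delimited text
#'
#' Reads a quantification-cycle table in either layout used in the field:
#' *wide* (first column the gene identifier, one column per sample) or
#' *long* (columns `gene`, `sample`, `ct`). The field separator is chosen
#' from the file extension: tab for `.tsv`/`.txt`, comma otherwise. Numbers
#' must use `'.'` as the decimal separator.
#'
#' @param path Path to the Ct table.
#' @param layout `"wide"`, `"long"`, or `"auto"` (long is recognised by its
#'   `gene`/`sample`/`ct` header).
#' @param annotation Optional path to a two-column `sample,group` file
#'   mapping every sample to its group label. Samples present in only one
#'   of the two files are an error.
#' @param group Optional group labels passed straight to [ct_matrix()]
#'   when no annotation file is given.
#'
#' @return A validated [ct_matrix()].
#' @details Duplicate `(gene, sample)` entries, missing cells and
#'   non-numeric Ct values are hard errors that name the offending gene,
#'   sample or file line; the downstream algorithms assume a complete
#'   matrix and nothing is imputed.
#' @seealso [write_ct()]
#' @export
read_ct <- function(path, layout = c("auto", "wide", "long"),
                    annotation = NULL, group = NULL) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stopf("file not found: %s", path)
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, sep = sep, header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE, quote = "\"",
                           comment.char = "", blank.lines.skip = TRUE)
  if (nrow(raw) == 0L) stopf("no data rows in %s", path)

  if (layout == "auto") {
    layout <- if (ncol(raw) == 3L &&
                  all(tolower(names(raw)) == c("gene", "sample", "ct")))
      "long" else "wide"
  }

  if (layout == "long") {
    names(raw) <- tolower(names(raw))
    if (!all(c("gene", "sample", "ct") %in% names(raw)))
      stopf("long layout needs columns gene, sample, ct")
    key <- paste(raw$gene, raw$sample, sep = "\r")
    if (anyDuplicated(key)) {
      d <- strsplit(key[duplicated(key)][1], "\r")[[1]]
      stopf("duplicate entry for gene '%s', sample '%s'", d[1], d[2])
    }
    ct <- suppressWarnings(as.numeric(raw$ct))
    if (anyNA(ct)) {
      i <- which(is.na(ct))[1]
      stopf("non-numeric Ct '%s' at line %d of %s", raw$ct[i], i + 1L, path)
    }
    genes <- unique(raw$gene)
    samples <- unique(raw$sample)
    m <- matrix(NA_real_, length(genes), length(samples),
                dimnames = list(genes, samples))
    m[cbind(raw$gene, raw$sample)] <- ct
    if (anyNA(m)) {
      idx <- which(is.na(m), arr.ind = TRUE)[1, ]
      stopf("missing Ct value for gene '%s', sample '%s'",
            genes[idx[1]], samples[idx[2]])
    }
  } else {
    if (ncol(raw) < 2L) stopf("wide layout needs a gene column plus samples")
    genes <- raw[[1]]
    if (anyDuplicated(genes))
      stopf("duplicate entry for gene '%s'", genes[duplicated(genes)][1])
    samples <- names(raw)[-1]
    m <- matrix(NA_real_, length(genes), length(samples),
                dimnames = list(genes, samples))
    for (j in seq_along(samples)) {
      col <- raw[[j + 1L]]
      blank <- is.na(col) | !nzchar(trimws(col))
      if (any(blank))
        stopf("missing Ct value for gene '%s', sample '%s'",
              genes[which(blank)[1]], samples[j])
      v <- suppressWarnings(as.numeric(col))
      if (anyNA(v)) {
        i <- which(is.na(v))[1]
        stopf("non-numeric Ct '%s' at line %d of %s", col[i], i + 1L, path)
      }
      m[, j] <- v
    }
  }

  if (!is.null(annotation)) {
    ann <- utils::read.table(annotation,
                             sep = if (grepl("\\.(tsv|txt)$", annotation,
                                             ignore.case = TRUE)) "\t" else ",",
                             header = TRUE, stringsAsFactors = FALSE,
                             colClasses = "character")
    names(ann) <- tolower(names(ann))
    if (!all(c("sample", "group") %in% names(ann)))
      stopf("annotation needs columns sample, group")
    unknown <- setdiff(ann$sample, colnames(m))
    if (length(unknown))
      stopf("annotation refers to unknown sample(s): %s",
            paste(unknown, collapse = ", "))
    group <- stats::setNames(ann$group, ann$sample)
  }
  ct_matrix(m, group = group)
}

#' Write a Ct matrix to delimited text
#'
#' @param x A [ct_matrix()].
#' @param path Output path; tab-separated for `.tsv`/`.txt`, comma otherwise.
#' @param layout `"wide"` or `"long"` (see [read_ct()]).
#' @param annotation Optional path for a `sample,group` annotation file.
#' @return Invisibly, `path`.
#' @export
write_ct <- function(x, path, layout = c("wide", "long"), annotation = NULL) {
  x <- as_ct_input(x)
  layout <- match.arg(layout)
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  if (layout == "wide") {
    df <- data.frame(gene = rownames(x), as.matrix(x), check.names = FALSE)
  } else {
    df <- data.frame(gene = rep(rownames(x), times = ncol(x)),
                     sample = rep(colnames(x), each = nrow(x)),
                     ct = as.vector(unclass(x)[, , drop = FALSE]))
  }
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  if (!is.null(annotation)) {
    g <- ct_groups(x)
    utils::write.table(data.frame(sample = names(g), group = unname(g)),
                       annotation, sep = ",", row.names = FALSE, quote = FALSE,
                       fileEncoding = "UTF-8")
  }
  invisible(path)
}

#' Read per-gene amplification factors
#'
#' Reads a two-column `gene,amplification_factor` file giving the per-cycle
#' amplification factor E for each gene (2 means perfect doubling).
#'
#' @param path Path to the file (comma- or tab-separated by extension).
#' @return Named numeric vector of amplification factors, validated to lie
#'   in (1, 3].
#' @seealso [efficiency_from_slope()], [relative_quantity()]
#' @export
read_efficiency <- function(path) {
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stopf("efficiency file needs columns gene, amplification_factor")
  eff <- stats::setNames(as.numeric(df[[2]]), as.character(df[[1]]))
  check_efficiency(eff)
  eff
}

check_efficiency <- function(eff) {
  if (anyNA(eff) || any(eff <= 1) || any(eff > 3))
    stopf("amplification factors must lie in (1, 3]")
  invisible(eff)
}
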