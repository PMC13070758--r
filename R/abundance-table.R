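# Samples x taxa abundance container with rank-prefixed lineage names.

#' Construct an abundance table
#'
#' A light samples-by-taxa container for genus-level (or any-level)
#' abundances. Taxa are named by rank-prefixed lineage strings such as
#' `"k__Bacteria;p__Actinobacteriota;...;g__Bifidobacterium"`; plain
#' genus names are accepted too.
#'
#' @param values Numeric matrix, samples in rows, taxa in columns.
#' @param sample_ids Character vector of unique sample identifiers
#'   (defaults to rownames of `values`).
#' @param taxa Character vector of unique taxon names (defaults to
#'   colnames of `values`).
#' @param is_relative Logical; `TRUE` when rows are relative abundances
#'   summing to 1, `FALSE` for counts.
#'
#' @return An object of class `abundance_table`: a list with fields
#'   `values` (matrix with dimnames), `sample_ids`, `taxa`,
#'   `is_relative`.
#' @export
abundance_table <- function(values, sample_ids = rownames(values),
                            taxa = colnames(values), is_relative = FALSE) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("values must be numeric", call. = FALSE)
  if (is.null(sample_ids)) stop("sample_ids are required", call. = FALSE)
  if (is.null(taxa)) stop("taxa names are required", call. = FALSE)
  sample_ids <- as.character(sample_ids)
  taxa <- as.character(taxa)
  if (length(sample_ids) != nrow(values)) {
    stop("sample_ids length must match nrow(values)", call. = FALSE)
  }
  if (length(taxa) != ncol(values)) {
    stop("taxa length must match ncol(values)", call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicated sample id: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(taxa)) {
    stop("duplicated taxon: ",
         paste(unique(taxa[duplicated(taxa)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("abundances must be finite and non-negative", call. = FALSE)
  }
  if (isTRUE(is_relative)) {
    rs <- rowSums(values)
    bad <- which(abs(rs - 1) > 1e-9)
    if (length(bad)) {
      stop("relative abundance rows must sum to 1 (off for sample ",
           sample_ids[bad[1]], ")", call. = FALSE)
    }
  }
  dimnames(values) <- list(sample_ids, taxa)
  structure(list(values = values, sample_ids = sample_ids, taxa = taxa,
                 is_relative = isTRUE(is_relative)),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("<abundance_table> %d samples x %d taxa (%s)\n",
              length(x$sample_ids), length(x$taxa),
              if (x$is_relative) "relative" else "counts"))
  invisible(x)
}

#' @export
dim.abundance_table <- function(x) dim(x$values)

# Split a lineage string on ';' into named rank components ("k", "p",
# ..., "g", "s"); components without a rank prefix are dropped.
parse_lineage <- function(lineage) {
  parts <- trimws(strsplit(lineage, ";", fixed = TRUE)[[1]])
  parts <- parts[nzchar(parts)]
  has_prefix <- grepl("^[a-z]__", parts)
  if (length(parts) && !any(has_prefix)) {
    # plain genus-name mode: treat the whole string as a genus label
    return(c(g = lineage))
  }
  parts <- parts[has_prefix]
  ranks <- substr(parts, 1, 1)
  vals <- substring(parts, 4)
  stats::setNames(vals, ranks)
}

lineage_rank <- function(lineage, rank) {
  comp <- parse_lineage(lineage)
  if (rank %in% names(comp)) comp[[rank]] else NA_character_
}
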