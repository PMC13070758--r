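# Genus-level feature derivation: normalisation, genus collapse,
# prevalence/abundance filtering, the micro-balance log-ratio, Chao1,
# the Firmicutes/Bacteroidetes ratio and a rank-based differential
# screen.

#' Convert counts to relative abundances
#'
#' Divides every sample row by its total. Already-relative tables are
#' returned unchanged.
#'
#' @param table An [abundance_table()].
#' @return A relative [abundance_table()] whose rows sum to 1.
#' @export
to_relative <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  if (table$is_relative) return(table)
  rs <- rowSums(table$values)
  zero <- which(rs <= 0)
  if (length(zero)) {
    stop("sample ", table$sample_ids[zero[1]],
         " has zero total abundance; cannot normalise", call. = FALSE)
  }
  abundance_table(table$values / rs, table$sample_ids, table$taxa,
                  is_relative = TRUE)
}

#' Collapse taxa to the genus level
#'
#' Columns sharing a genus label are summed. Columns whose lineage has
#' no genus (empty `g__`) are labelled by their closest family as an
#' `f__<family>` proxy column. Per-sample totals are conserved exactly.
#' The mapping from collapsed columns back to their source taxa is kept
#' in the `"provenance"` attribute.
#'
#' @param table An [abundance_table()] with parseable lineage strings.
#' @return An [abundance_table()] at genus (or family-proxy) level.
#' @export
collapse_to_genus <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  labels <- vapply(table$taxa, function(tx) {
    comp <- parse_lineage(tx)
    if (!length(comp)) {
      stop("unparseable lineage string: '", tx, "'", call. = FALSE)
    }
    g <- if ("g" %in% names(comp)) comp[["g"]] else ""
    if (nzchar(g)) return(paste0("g__", g))
    f <- if ("f" %in% names(comp)) comp[["f"]] else ""
    if (nzchar(f)) return(paste0("f__", f))
    stop("lineage '", tx, "' has neither genus nor family", call. = FALSE)
  }, character(1))
  groups <- split(seq_along(labels), labels)
  # keep first-appearance order and a representative full lineage so
  # phylum information survives the collapse
  ord <- order(vapply(groups, min, integer(1)))
  groups <- groups[ord]
  new_names <- vapply(names(groups), function(lab) {
    rep_tax <- table$taxa[groups[[lab]][1]]
    comp <- parse_lineage(rep_tax)
    keep <- names(comp) %in% c("k", "p", "c", "o", "f")
    upper <- paste(paste0(names(comp)[keep], "__", comp[keep]),
                   collapse = ";")
    lab_rank <- substr(lab, 1, 1)
    if (lab_rank == "f" || !nzchar(upper)) {
      # family proxy (or plain-name input): label stands alone
      if (!nzchar(upper)) lab else sub(";f__[^;]*$", paste0(";", lab), upper)
    } else {
      paste(upper, lab, sep = ";")
    }
  }, character(1))
  vals <- vapply(groups, function(idx) {
    rowSums(table$values[, idx, drop = FALSE])
  }, numeric(nrow(table$values)))
  if (length(table$sample_ids) == 1L) vals <- matrix(vals, nrow = 1)
  out <- abundance_table(vals, table$sample_ids, unname(new_names),
                         is_relative = table$is_relative)
  attr(out, "provenance") <- stats::setNames(
    lapply(groups, function(idx) table$taxa[idx]), unname(new_names))
  out
}

#' Filter taxa by prevalence and mean relative abundance
#'
#' Retains taxa whose prevalence (fraction of samples with strictly
#' positive abundance) is at least `min_prevalence` AND whose mean
#' relative abundance is at least `min_mean_rel_abundance`. Both bounds
#' are inclusive: the exclusion rule is strictly-below. Idempotent.
#'
#' @param table A relative [abundance_table()].
#' @param min_prevalence Minimum prevalence fraction (default 0.15).
#' @param min_mean_rel_abundance Minimum mean relative abundance
#'   (default 0.001, i.e. 0.1%).
#' @return The filtered [abundance_table()]; the per-taxon filter report
#'   (columns `taxon`, `prevalence`, `mean_abundance`, `kept`) is
#'   attached as attribute `"filter_report"`. An empty result triggers a
#'   warning, not an error.
#' @export
filter_taxa <- function(table, min_prevalence = 0.15,
                        min_mean_rel_abundance = 0.001) {
  stopifnot(inherits(table, "abundance_table"))
  if (!table$is_relative) {
    stop("filter_taxa expects a relative table; call to_relative() first",
         call. = FALSE)
  }
  if (min_prevalence < 0 || min_prevalence > 1 ||
      min_mean_rel_abundance < 0 || min_mean_rel_abundance > 1) {
    stop("filter thresholds must be in [0, 1]", call. = FALSE)
  }
  prev <- colMeans(table$values > 0)
  mab <- colMeans(table$values)
  keep <- prev >= min_prevalence & mab >= min_mean_rel_abundance
  report <- data.frame(taxon = table$taxa, prevalence = unname(prev),
                       mean_abundance = unname(mab), kept = unname(keep),
                       stringsAsFactors = FALSE)
  if (!any(keep)) {
    warning("no taxa pass the prevalence/abundance filter", call. = FALSE)
  }
  vals <- table$values[, keep, drop = FALSE]
  # rows no longer sum to 1 after dropping columns
  out <- abundance_table(vals, table$sample_ids, table$taxa[keep],
                         is_relative = FALSE)
  out$is_relative <- table$is_relative
  attr(out, "filter_report") <- report
  out
}

match_genus <- function(table, genus) {
  hit <- which(table$taxa == genus)
  if (!length(hit)) {
    wanted <- sub("^g__", "", genus)
    hit <- which(vapply(table$taxa, function(tx) {
      g <- lineage_rank(tx, "g")
      identical(g, wanted) || identical(tx, wanted)
    }, logical(1)))
  }
  hit
}

#' Rank candidate taxa by mean abundance
#'
#' Sort candidate genera by descending mean (baseline) relative
#' abundance; ties are broken lexicographically for determinism.
#'
#' @param table A relative [abundance_table()].
#' @param candidates Character vector of taxon names (full lineages or
#'   `g__Genus` / plain genus labels) present in `table`.
#' @return The candidates reordered, as named in `table`.
#' @export
rank_by_mean_abundance <- function(table, candidates) {
  stopifnot(inherits(table, "abundance_table"))
  idx <- vapply(candidates, function(cand) {
    hit <- match_genus(table, cand)
    if (!length(hit)) {
      stop("candidate taxon not found in table: ", cand, call. = FALSE)
    }
    hit[1]
  }, integer(1))
  means <- colMeans(table$values[, idx, drop = FALSE])
  nms <- table$taxa[idx]
  nms[order(-means, nms)]
}

#' Micro-balance specification
#'
#' Defines the log-ratio balance feature: one numerator genus against
#' the geometric mean of the denominator genera, with pseudocount
#' `epsilon` added to each relative abundance before taking logs.
#'
#' @param numerator Numerator genus name.
#' @param denominators Character vector of denominator genus names
#'   (two in the canonical balance).
#' @param epsilon Positive pseudocount added to relative abundances;
#'   default `1e-6`.
#' @return An object of class `balance_spec`.
#' @export
#' @examples
#' balance_spec("g__Bifidobacterium",
#'              c("g__Phascolarctobacterium", "g__Lachnoclostridium"))
balance_spec <- function(numerator, denominators, epsilon = 1e-6) {
  if (!is.character(numerator) || length(numerator) != 1) {
    stop("numerator must be a single genus name", call. = FALSE)
  }
  if (!is.character(denominators) || !length(denominators)) {
    stop("denominators must be a non-empty character vector", call. = FALSE)
  }
  if (numerator %in% denominators) {
    stop("numerator may not appear among denominators", call. = FALSE)
  }
  if (!is.numeric(epsilon) || epsilon <= 0) {
    stop("epsilon must be positive", call. = FALSE)
  }
  structure(list(numerator = numerator, denominators = denominators,
                 epsilon = epsilon),
            class = "balance_spec")
}

#' Compute the micro-balance log-ratio feature
#'
#' For each sample, with relative abundances `b` (numerator) and
#' `d1..dk` (denominators) and pseudocount `eps`:
#' `log(b + eps) - mean(log(d1 + eps), ..., log(dk + eps))` using the
#' natural logarithm. Higher values indicate a community tilted toward
#' the numerator genus. An all-zero sample gives exactly 0 by symmetry.
#'
#' @param table A relative [abundance_table()] containing every genus
#'   named in `spec`.
#' @param spec A [balance_spec()].
#' @return Named numeric vector of per-sample balance values.
#' @export
compute_balance <- function(table, spec) {
  stopifnot(inherits(table, "abundance_table"), inherits(spec, "balance_spec"))
  if (!table$is_relative) {
    stop("compute_balance expects relative abundances", call. = FALSE)
  }
  col_of <- function(genus) {
    hit <- match_genus(table, genus)
    if (!length(hit)) {
      stop("balance taxon absent from table: ", genus, call. = FALSE)
    }
    table$values[, hit[1]]
  }
  num <- log(col_of(spec$numerator) + spec$epsilon)
  den_logs <- vapply(spec$denominators,
                     function(g) log(col_of(g) + spec$epsilon),
                     numeric(nrow(table$values)))
  if (nrow(table$values) == 1L) den_logs <- matrix(den_logs, nrow = 1)
  den <- rowMeans(den_logs)
  stats::setNames(num - den, table$sample_ids)
}

#' Firmicutes/Bacteroidetes ratio
#'
#' Per-sample ratio of total Firmicutes (Bacillota) to total
#' Bacteroidetes (Bacteroidota) abundance, resolved from lineage phylum
#' labels; updated-nomenclature synonyms are accepted. Samples with zero
#' Bacteroidetes are returned as `Inf` and excluded from the mean.
#'
#' @param table An [abundance_table()] whose taxa carry phylum labels.
#' @return A list with `per_sample` (named vector) and `mean_ratio`
#'   (mean over finite values).
#' @export
fb_ratio <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  syn_f <- c("Firmicutes", "Bacillota")
  syn_b <- c("Bacteroidetes", "Bacteroidota")
  phyla <- vapply(table$taxa, lineage_rank, character(1), rank = "p")
  is_f <- phyla %in% syn_f
  is_b <- phyla %in% syn_b
  if (!any(is_f) || !any(is_b)) {
    stop("table contains no Firmicutes and/or no Bacteroidetes taxa",
         call. = FALSE)
  }
  f_tot <- rowSums(table$values[, is_f, drop = FALSE])
  b_tot <- rowSums(table$values[, is_b, drop = FALSE])
  ratio <- stats::setNames(f_tot / b_tot, table$sample_ids)
  list(per_sample = ratio, mean_ratio = mean(ratio[is.finite(ratio)]))
}

#' Chao1 richness estimator
#'
#' Bias-corrected Chao1 for one sample of taxon counts:
#' `S_obs + F1*(F1-1) / (2*(F2+1))` where `F1` and `F2` are the numbers
#' of singletons and doubletons. Requires integer counts; relative
#' abundances have no singleton structure and are rejected.
#'
#' @param counts Non-negative integer vector of per-taxon counts for a
#'   single sample.
#' @return Numeric richness estimate; always `>= S_obs`.
#' @export
#' @examples
#' chao1(c(1, 1, 2, 5)) # 4.5
chao1 <- function(counts) {
  if (!is.numeric(counts) || any(!is.finite(counts)) || any(counts < 0)) {
    stop("counts must be finite and non-negative", call. = FALSE)
  }
  if (any(abs(counts - round(counts)) > 1e-8)) {
    stop("Chao1 requires integer counts, not relative abundances",
         call. = FALSE)
  }
  counts <- round(counts)
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' Rank-based differential abundance screen
#'
#' A deliberately simplified candidate-nomination screen in the spirit
#' of LEfSe: per genus, a two-sample Wilcoxon rank-sum p-value between
#' groups plus an effect score `log10(|mean difference| * 1e6)` on the
#' parts-per-million scale, so a difference of 1e-4 in relative
#' abundance scores 2.0. A genus is flagged "responsive" when
#' `p < 0.05` and the score exceeds `score_threshold`. This nominates
#' candidate taxa only; it is not a full LEfSe (no taxonomy hierarchy,
#' no LDA bootstrap, no cladograms).
#'
#' @param table_a,table_b Relative [abundance_table()]s for the two
#'   groups, with identical taxa.
#' @param score_threshold Effect-score threshold (default 2.0).
#' @return data.frame with columns `taxon`, `p_value`, `effect_score`,
#'   `direction` (+1 when group A has the higher mean, -1 otherwise, 0
#'   for ties/degenerate) and `flagged`.
#' @export
differential_screen <- function(table_a, table_b, score_threshold = 2.0) {
  stopifnot(inherits(table_a, "abundance_table"),
            inherits(table_b, "abundance_table"))
  if (!identical(table_a$taxa, table_b$taxa)) {
    stop("the two tables must share an identical taxa set", call. = FALSE)
  }
  res <- lapply(seq_along(table_a$taxa), function(j) {
    xa <- table_a$values[, j]
    xb <- table_b$values[, j]
    d <- mean(xa) - mean(xb)
    if (all(xa == xa[1]) && all(xb == xb[1]) && xa[1] == xb[1]) {
      return(data.frame(taxon = table_a$taxa[j], p_value = NA_real_,
                        effect_score = -Inf, direction = 0,
                        flagged = FALSE, stringsAsFactors = FALSE))
    }
    p <- suppressWarnings(stats::wilcox.test(xa, xb)$p.value)
    score <- log10(max(abs(d), 1e-10) * 1e6)
    data.frame(taxon = table_a$taxa[j], p_value = p, effect_score = score,
               direction = sign(d),
               flagged = is.finite(p) && p < 0.05 && score > score_threshold,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
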