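#' Label-by-seed contingency counts
#'
#' The 2x2 information behind both decoding directions: how many database
#' experiments exist in total, how many carry a given taxonomy label, how
#' many activate the seed, and how many do both. All conditional and
#' marginal probabilities used by forward and reverse inference derive
#' from these four counts.
#'
#' @param label taxonomy label.
#' @param n_total database experiment count.
#' @param n_label experiments carrying the label.
#' @param n_seed experiments activating the seed.
#' @param n_both experiments with the label AND activating the seed.
#' @return A list of class `label_contingency`.
#' @export
label_contingency <- function(label, n_total, n_label, n_seed, n_both) {
  n_total <- as.integer(n_total); n_label <- as.integer(n_label)
  n_seed <- as.integer(n_seed); n_both <- as.integer(n_both)
  if (n_total < 1L) stop("n_total must be >= 1")
  if (n_both < 0L || n_both > min(n_label, n_seed) ||
      max(n_label, n_seed) > n_total)
    stop("counts must satisfy 0 <= n_both <= min(n_label, n_seed) <= n_total")
  structure(list(label = as.character(label), n_total = n_total,
                 n_label = n_label, n_seed = n_seed, n_both = n_both),
            class = "label_contingency")
}

# optional hierarchical expansion: "A.B.C" also counts as "A.B" and "A"
.expand_prefixes <- function(labels) {
  out <- unlist(lapply(labels, function(l) {
    parts <- strsplit(l, ".", fixed = TRUE)[[1]]
    vapply(seq_along(parts), function(k)
      paste(parts[seq_len(k)], collapse = "."), "")
  }))
  unique(out)
}

.experiment_labels <- function(e, expand_prefixes) {
  if (expand_prefixes) .expand_prefixes(e$labels) else e$labels
}

#' Build the contingency counts for one label and one seed
#'
#' @param db a [coordinate_database()].
#' @param seed a [seed_region()].
#' @param label taxonomy label (a label absent from the database yields
#'   zero counts with a warning).
#' @param selected_ids optional precomputed ids of the seed-activating
#'   experiments (from [select_experiments_by_seed()]), to avoid repeated
#'   selection across labels.
#' @param expand_prefixes when `TRUE`, an experiment labeled with a
#'   subcategory (`"Cognition.Memory"`) also counts for its parents
#'   (`"Cognition"`).
#' @return A [label_contingency()].
#' @export
build_contingency <- function(db, seed, label, selected_ids = NULL,
                              expand_prefixes = FALSE) {
  if (length(db) == 0L) stop("database is empty")
  if (is.null(selected_ids))
    selected_ids <- db_ids(suppressWarnings(select_experiments_by_seed(db, seed)))
  has_label <- vapply(db$experiments, function(e)
    label %in% .experiment_labels(e, expand_prefixes), TRUE)
  if (!any(has_label))
    warning("label '", label, "' does not occur in the database")
  in_seed <- db_ids(db) %in% selected_ids
  label_contingency(label, length(db), sum(has_label), sum(in_seed),
                    sum(has_label & in_seed))
}

#' Forward inference: P(activation | task) against the base rate
#'
#' Exact one-sided binomial test of whether experiments carrying the label
#' activate the seed more often than the database-wide base rate:
#' `p = P(X >= n_both)` with `X ~ Binomial(n_label, n_seed / n_total)`.
#' Significant when `p < alpha` and the enrichment is positive.
#'
#' @param c a [label_contingency()].
#' @param alpha significance threshold.
#' @return A list: `p`, `significant`, `p_activation_given_task`
#'   (`n_both / n_label`), `base_rate` (`n_seed / n_total`).
#' @export
forward_inference <- function(c, alpha = 0.001) {
  stopifnot(inherits(c, "label_contingency"))
  base <- c$n_seed / c$n_total
  if (c$n_label < 1L)
    return(list(p = NA_real_, significant = FALSE,
                p_activation_given_task = NA_real_, base_rate = base))
  p <- stats::pbinom(c$n_both - 1L, c$n_label, base, lower.tail = FALSE)
  pat <- c$n_both / c$n_label
  list(p = p, significant = (p < alpha) && (pat > base),
       p_activation_given_task = pat, base_rate = base)
}

#' Reverse inference: P(task | activation) and its association test
#'
#' The posterior probability of the label given seed activation follows
#' Bayes' rule, `P(T|A) = P(A|T) P(T) / P(A)`, which for contingency
#' counts reduces exactly to `n_both / n_seed`. The label-activation
#' association is tested with the standard Pearson chi-square on the 2x2
#' table (no continuity correction); tables with an expected cell count
#' below 5 are flagged. Significant when `p < alpha` and the posterior
#' exceeds the label's prior `P(T)`.
#'
#' @param c a [label_contingency()].
#' @param alpha significance threshold.
#' @return A list: `chi2`, `p`, `posterior` (P(Task|Activation)), `prior`
#'   (P(Task)), `significant`, `low_expected_count`, `undefined` (degenerate
#'   margin).
#' @export
reverse_inference <- function(c, alpha = 0.001) {
  stopifnot(inherits(c, "label_contingency"))
  o <- matrix(c(c$n_both, c$n_seed - c$n_both,
                c$n_label - c$n_both,
                c$n_total - c$n_label - c$n_seed + c$n_both), 2, 2)
  prior <- c$n_label / c$n_total
  if (any(rowSums(o) == 0L) || any(colSums(o) == 0L))
    return(list(chi2 = NA_real_, p = NA_real_,
                posterior = if (c$n_seed > 0) c$n_both / c$n_seed else NA_real_,
                prior = prior, significant = FALSE,
                low_expected_count = NA, undefined = TRUE))
  e <- outer(rowSums(o), colSums(o)) / c$n_total
  chi2 <- sum((o - e)^2 / e)
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  posterior <- c$n_both / c$n_seed
  list(chi2 = chi2, p = p, posterior = posterior, prior = prior,
       significant = (p < alpha) && (posterior > prior),
       low_expected_count = any(e < 5), undefined = FALSE)
}

#' Functional decoding table of one seed
#'
#' One row per taxonomy label, combining forward (binomial) and reverse
#' (chi-square + Bayes posterior) inference; the `robust` flag marks labels
#' significant in both directions, the convention for reporting a seed's
#' functional profile.
#'
#' @param db a [coordinate_database()].
#' @param seed a [seed_region()].
#' @param taxonomy labels to test (defaults to every label in the
#'   database).
#' @param alpha_forward,alpha_reverse per-direction significance levels.
#' @param expand_prefixes see [build_contingency()].
#' @return A data frame of class `decoding_table` with the counts,
#'   probabilities, statistics, p-values and flags per label; the seed
#'   name is kept in attribute `seed_name`.
#' @export
decode_seed <- function(db, seed, taxonomy = db_labels(db),
                        alpha_forward = 0.001, alpha_reverse = 0.001,
                        expand_prefixes = FALSE) {
  if (length(taxonomy) == 0L) stop("taxonomy is empty")
  selected <- db_ids(suppressWarnings(select_experiments_by_seed(db, seed)))
  rows <- lapply(taxonomy, function(lb) {
    cc <- suppressWarnings(
      build_contingency(db, seed, lb, selected_ids = selected,
                        expand_prefixes = expand_prefixes))
    fw <- forward_inference(cc, alpha_forward)
    rv <- reverse_inference(cc, alpha_reverse)
    data.frame(label = lb, n_total = cc$n_total, n_label = cc$n_label,
               n_seed = cc$n_seed, n_both = cc$n_both,
               base_rate = fw$base_rate,
               p_activation_given_task = fw$p_activation_given_task,
               p_task = rv$prior, p_task_given_activation = rv$posterior,
               forward_p = fw$p, forward_significant = fw$significant,
               reverse_chi2 = rv$chi2, reverse_p = rv$p,
               reverse_significant = rv$significant,
               low_expected_count = rv$low_expected_count,
               robust = fw$significant && rv$significant)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  attr(tab, "seed_name") <- seed$name
  class(tab) <- c("decoding_table", class(tab))
  tab
}

# The 2x2 construction for contrast decoding, isolated so it can be
# substituted: experiments activating exactly one of the two seeds,
# cross-tabulated as (seed A vs seed B) x (label vs not).
.contrast_table <- function(label, exps_a_only, exps_b_only,
                            expand_prefixes = FALSE) {
  la <- sum(vapply(exps_a_only, function(e)
    label %in% .experiment_labels(e, expand_prefixes), TRUE))
  lb <- sum(vapply(exps_b_only, function(e)
    label %in% .experiment_labels(e, expand_prefixes), TRUE))
  matrix(c(la, length(exps_a_only) - la,
           lb, length(exps_b_only) - lb), 2, 2, byrow = TRUE)
}

#' Contrast decoding between two seeds
#'
#' Within the pooled set of experiments activating either seed, every label
#' is tested for differential association between the seeds with a Pearson
#' chi-square on the (seed A vs seed B) x (label vs not) table, restricted
#' to experiments activating exactly one seed. P-values are
#' Benjamini-Hochberg corrected across labels at rate `q`, and a label is
#' reported for a seed only if it is also `robust` in that seed's
#' individual [decode_seed()] profile (the masking rule).
#'
#' @param db a [coordinate_database()].
#' @param seed_a,seed_b the two [seed_region()]s.
#' @param taxonomy labels to test (defaults to all database labels).
#' @param q false-discovery rate across labels.
#' @param decode_a,decode_b optional precomputed [decode_seed()] tables
#'   (recomputed when absent).
#' @param expand_prefixes see [build_contingency()].
#' @param ... passed to [decode_seed()] when recomputing.
#' @return A list of class `contrast_decoding_result` with data frames
#'   `a` and `b`: per label the counts, chi-square, raw and adjusted
#'   p-values, the favored direction and the final `reported` flag.
#' @export
contrast_decoding <- function(db, seed_a, seed_b, taxonomy = db_labels(db),
                              q = 0.05, decode_a = NULL, decode_b = NULL,
                              expand_prefixes = FALSE, ...) {
  ids_a <- db_ids(suppressWarnings(select_experiments_by_seed(db, seed_a)))
  ids_b <- db_ids(suppressWarnings(select_experiments_by_seed(db, seed_b)))
  if (length(ids_a) == 0L && length(ids_b) == 0L)
    stop("neither seed selects any experiment")
  if (is.null(decode_a))
    decode_a <- decode_seed(db, seed_a, taxonomy,
                            expand_prefixes = expand_prefixes, ...)
  if (is.null(decode_b))
    decode_b <- decode_seed(db, seed_b, taxonomy,
                            expand_prefixes = expand_prefixes, ...)
  all_ids <- db_ids(db)
  ea <- db$experiments[all_ids %in% setdiff(ids_a, ids_b)]
  eb <- db$experiments[all_ids %in% setdiff(ids_b, ids_a)]
  stats_per_label <- lapply(taxonomy, function(lb) {
    o <- .contrast_table(lb, ea, eb, expand_prefixes)
    if (any(rowSums(o) == 0L) || any(colSums(o) == 0L))
      return(list(chi2 = NA_real_, p = NA_real_, pa = NA_real_,
                  pb = NA_real_))
    e <- outer(rowSums(o), colSums(o)) / sum(o)
    list(chi2 = sum((o - e)^2 / e),
         p = stats::pchisq(sum((o - e)^2 / e), 1, lower.tail = FALSE),
         pa = o[1, 1] / sum(o[1, ]), pb = o[2, 1] / sum(o[2, ]))
  })
  p_raw <- vapply(stats_per_label, `[[`, 0, "p")
  p_adj <- stats::p.adjust(p_raw, method = "BH")
  mk <- function(which_seed, decode_tab) {
    fav <- if (which_seed == "a")
      vapply(stats_per_label, function(s) isTRUE(s$pa > s$pb), TRUE)
    else
      vapply(stats_per_label, function(s) isTRUE(s$pb > s$pa), TRUE)
    robust <- decode_tab$robust[match(taxonomy, decode_tab$label)]
    data.frame(label = taxonomy,
               p_label_given_a = vapply(stats_per_label, `[[`, 0, "pa"),
               p_label_given_b = vapply(stats_per_label, `[[`, 0, "pb"),
               chi2 = vapply(stats_per_label, `[[`, 0, "chi2"),
               p = p_raw, p_fdr = p_adj,
               favored = fav,
               robust_individual = robust,
               reported = !is.na(p_adj) & p_adj < q & fav & robust)
  }
  structure(list(a = mk("a", decode_a), b = mk("b", decode_b),
                 seed_a = attr(decode_a, "seed_name"),
                 seed_b = attr(decode_b, "seed_name"), q = q),
            class = "contrast_decoding_result")
}

#' Labels robustly associated with both seeds
#'
#' Intersection of the `robust` label sets (significant in both forward
#' and reverse inference) of two decoding tables over the same taxonomy.
#'
#' @param table_a,table_b [decode_seed()] tables over identical label
#'   sets.
#' @return Character vector of labels.
#' @export
conjunction_decoding <- function(table_a, table_b) {
  if (!setequal(table_a$label, table_b$label))
    stop("decoding tables cover different taxonomies")
  intersect(table_a$label[table_a$robust], table_b$label[table_b$robust])
}

#' Write a decoding table as TSV
#' @param tab a [decode_seed()] table.
#' @param path output path.
#' @export
write_decoding_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
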