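## Repeat-type enrichment between genome groups: abundance (proportional
## length) and conservation (Kimura divergence), with the
## Shapiro -> (log) -> Levene -> (Student | Welch) decision tree and
## multiple-testing adjustment.

#' Per-genome repeat-type table
#'
#' Summarises each genome's annotated repeats by repeat type: the
#' proportional length relative to total assembled sequence and the
#' mean Kimura divergence (percent) of the type's copies.
#'
#' @param genomes list of [GenomeRecord-class] objects.
#' @return data.frame with columns `genome_id`, `repeat_type`,
#'   `repeat_class`, `proportion`, `kimura`.
#' @export
repeatTypeTable <- function(genomes) {
  rows <- lapply(genomes, function(g) {
    feats <- genomeFeatures(g)
    reps <- feats[feats$type == "repeat"]
    if (!length(reps)) return(NULL)
    if (is.null(reps$repeat_type))
      .stopf("repeat features of %s lack repeat_type", genomeId(g))
    total <- sum(Biostrings::width(scaffolds(g)))
    byType <- split(seq_along(reps), reps$repeat_type)
    do.call(rbind, lapply(names(byType), function(tp) {
      idx <- byType[[tp]]
      merged <- GenomicRanges::reduce(reps[idx], ignore.strand = TRUE)
      kim <- if (is.null(reps$kimura_divergence)) NA_real_
             else mean(reps$kimura_divergence[idx], na.rm = TRUE)
      data.frame(genome_id = genomeId(g), repeat_type = tp,
                 repeat_class = reps$repeat_class[idx][1L],
                 proportion = sum(Biostrings::width(merged)) / total,
                 kimura = kim, stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Repeat types shared by every genome of a group
#'
#' Types with non-zero proportion in every member.
#'
#' @param table data.frame from [repeatTypeTable()].
#' @param group genome ids.
#' @return character vector of repeat types.
#' @export
sharedRepeatTypes <- function(table, group) {
  if (!length(group)) .stopf("empty group")
  present <- table[table$genome_id %in% group & table$proportion > 0, ]
  tab <- table(unique(present[c("genome_id", "repeat_type")])$repeat_type)
  sort(names(tab)[tab == length(group)])
}

.shapiroP <- function(x) {
  if (length(x) < 3L || length(unique(x)) < 2L) return(NA_real_)
  tryCatch(stats::shapiro.test(x)$p.value, error = function(e) NA_real_)
}

.leveneP <- function(a, b) {
  df <- data.frame(v = c(a, b),
                   g = factor(rep(c("A", "B"), c(length(a), length(b)))))
  p <- tryCatch(car::leveneTest(v ~ g, data = df,
                                center = stats::median)[1L, "Pr(>F)"],
                error = function(e) NA_real_)
  as.numeric(p)
}

#' Differential repeat-type test between two genome groups
#'
#' For each repeat type shared by every genome of both groups, compares
#' the chosen metric (`proportion` of assembly length, or `kimura`
#' divergence) between groups with the decision tree: Shapiro-Wilk on
#' pooled within-group residuals at `alpha` decides whether values are
#' log-transformed (zeros replaced by half the smallest positive value
#' of the metric); median-centred Levene at `alpha` decides between the
#' two-sided Student's t-test (equal variance) and Welch's t-test;
#' p-values are then adjusted across all tested types per metric
#' (Benjamini-Hochberg by default). Types with zero within-group
#' variance in both groups but differing values are skipped with a
#' reason; types identical everywhere get `p = 1`.
#'
#' @param table data.frame from [repeatTypeTable()].
#' @param groupA,groupB genome ids of the two groups (each >= 2).
#' @param metric `"proportion"` or `"kimura"`.
#' @param alpha significance and gate level, default 0.05.
#' @param adjust multiple-testing method, `"BH"` (default) or
#'   `"bonferroni"` (any [stats::p.adjust()] method).
#' @param types repeat types to test; defaults to the types shared by
#'   every genome of both groups.
#' @return data.frame, one row per type: `repeat_type`, `repeat_class`,
#'   `metric`, `transform_applied`, `shapiro_p`, `variance_test_p`,
#'   `test_used`, `raw_p`, `adjusted_p`, `direction` (sign of mean(A) -
#'   mean(B)), `significant`, `reason`.
#' @export
enrichmentTest <- function(table, groupA, groupB,
                           metric = c("proportion", "kimura"),
                           alpha = 0.05, adjust = "BH", types = NULL) {
  metric <- match.arg(metric)
  if (length(groupA) < 2L || length(groupB) < 2L)
    .stopf("each group needs >= 2 genomes")
  if (is.null(types))
    types <- sharedRepeatTypes(table, c(groupA, groupB))
  if (!length(types)) .stopf("no shared repeat types to test")
  posVals <- table[[metric]][table[[metric]] > 0 & !is.na(table[[metric]])]
  eps <- if (length(posVals)) min(posVals) / 2 else .Machine$double.eps
  getVals <- function(tp, grp) {
    v <- vapply(grp, function(g) {
      row <- table[table$genome_id == g & table$repeat_type == tp, ]
      if (nrow(row)) row[[metric]][1L]
      else if (metric == "proportion") 0 else NA_real_
    }, 0)
    v
  }
  rows <- lapply(types, function(tp) {
    cls <- table$repeat_class[table$repeat_type == tp][1L]
    a <- getVals(tp, groupA); b <- getVals(tp, groupB)
    base <- data.frame(repeat_type = tp, repeat_class = cls,
                       metric = metric, transform_applied = "none",
                       shapiro_p = NA_real_, variance_test_p = NA_real_,
                       test_used = NA_character_, raw_p = NA_real_,
                       adjusted_p = NA_real_,
                       direction = sign(mean(a) - mean(b)),
                       significant = FALSE, reason = "",
                       stringsAsFactors = FALSE)
    if (anyNA(c(a, b))) {
      base$reason <- "missing values"
      return(base)
    }
    if (length(unique(c(a, b))) == 1L) {
      base$test_used <- "student"; base$raw_p <- 1
      base$reason <- "identical values"
      return(base)
    }
    if (stats::var(a) == 0 && stats::var(b) == 0) {
      base$reason <- "zero within-group variance in both groups"
      return(base)
    }
    resid <- c(a - mean(a), b - mean(b))
    sp <- .shapiroP(resid)
    base$shapiro_p <- sp
    if (!is.na(sp) && sp < alpha) {
      base$transform_applied <- "log"
      a[a == 0] <- eps; b[b == 0] <- eps
      a <- log(a); b <- log(b)
    }
    lp <- .leveneP(a, b)
    base$variance_test_p <- lp
    welch <- !is.na(lp) && lp < alpha
    base$test_used <- if (welch) "welch" else "student"
    tt <- tryCatch(stats::t.test(a, b, var.equal = !welch,
                                 alternative = "two.sided"),
                   error = function(e) NULL)
    if (is.null(tt)) {
      base$reason <- "t-test failed"
      return(base)
    }
    base$raw_p <- tt$p.value
    base$direction <- sign(mean(a) - mean(b))
    base
  })
  out <- do.call(rbind, rows)
  tested <- !is.na(out$raw_p)
  out$adjusted_p[tested] <- stats::p.adjust(out$raw_p[tested],
                                            method = adjust)
  out$significant <- !is.na(out$adjusted_p) & out$adjusted_p <= alpha
  out
}

#' Class-level summary of significant repeat types
#'
#' Counts significant repeat types per repeat class. A type significant
#' under both metrics is counted once, with per-metric flags retained.
#'
#' @param results one or more data.frames from [enrichmentTest()]
#'   (e.g. proportion and kimura results `rbind`-ed together).
#' @return data.frame with columns `repeat_class`, `n_significant`,
#'   `percent`, `n_proportion`, `n_kimura`, `n_both`; zero rows when
#'   nothing is significant.
#' @export
summariseByClass <- function(results) {
  sig <- results[results$significant, , drop = FALSE]
  if (!nrow(sig))
    return(data.frame(repeat_class = character(),
                      n_significant = integer(), percent = numeric(),
                      n_proportion = integer(), n_kimura = integer(),
                      n_both = integer(), stringsAsFactors = FALSE))
  byType <- split(sig, sig$repeat_type)
  typeRows <- do.call(rbind, lapply(byType, function(x)
    data.frame(repeat_type = x$repeat_type[1L],
               repeat_class = x$repeat_class[1L],
               prop_sig = "proportion" %in% x$metric,
               kim_sig = "kimura" %in% x$metric,
               stringsAsFactors = FALSE)))
  total <- nrow(typeRows)
  byClass <- split(typeRows, typeRows$repeat_class)
  out <- do.call(rbind, lapply(byClass, function(x)
    data.frame(repeat_class = x$repeat_class[1L],
               n_significant = nrow(x),
               percent = 100 * nrow(x) / total,
               n_proportion = sum(x$prop_sig & !x$kim_sig),
               n_kimura = sum(x$kim_sig & !x$prop_sig),
               n_both = sum(x$prop_sig & x$kim_sig),
               stringsAsFactors = FALSE)))
  out <- out[order(-out$n_significant), ]
  rownames(out) <- NULL
  out
}
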