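#' Immunophenotype table of xenograft lymphoproliferations
#'
#' Machine-readable per-xenograft marker, Ig light chain and EBER calls. The
#' marker vocabulary is closed: \code{"+"} (positive), \code{"-"} (negative),
#' \code{"#"} (focal/partial staining, kept as its own category and never
#' folded into + or -), and \code{"unavailable"} for samples without
#' histology. Ig codes are \code{"K"}, \code{"L"}, a parenthesised second
#' chain for dual expression (\code{"K (L)"}, \code{"L (K)"}), or
#' \code{"unavailable"}.
#'
#' @slot data data.frame with columns patient, region, one per stain, ig.
#' @slot stains character vector, stain column order as loaded.
#' @export
setClass("PhenotypeTable", representation(data = "data.frame",
                                          stains = "character"))

setMethod("show", "PhenotypeTable", function(object) {
  cat(sprintf("PhenotypeTable: %d xenografts, %d stains (%s...)\n",
              nrow(object@data), length(object@stains),
              paste(utils::head(object@stains, 4), collapse = ", ")))
})

#' @rdname PhenotypeTable-class
#' @param table a \code{PhenotypeTable}.
#' @export
phenotypeData <- function(table) table@data
#' @rdname PhenotypeTable-class
#' @export
phenotypeStains <- function(table) table@stains

markerVocabulary <- c("+", "-", "#", "unavailable")
igVocabulary <- c("K", "L", "K (L)", "L (K)", "unavailable")

#' Load a phenotype table from CSV
#'
#' Expects a header \code{patient,region,<stains...>,ig}. Every marker call
#' and Ig code is validated against the closed vocabulary; a violation is a
#' parse error naming the offending row and column.
#'
#' @param path CSV file path. The bundled cohort fixture ships as
#'   \code{system.file("extdata", "table1_phenotypes.csv",
#'   package = "slideOverview")}.
#' @return A \linkS4class{PhenotypeTable}.
#' @export
loadPhenotypeTable <- function(path) {
  if (!file.exists(path))
    soStop(sprintf("phenotype table not found: %s", path), "parseError")
  df <- tryCatch(utils::read.csv(path, colClasses = "character",
                                 check.names = FALSE, strip.white = TRUE),
                 error = function(e)
                   soStop(sprintf("cannot parse CSV %s: %s", path,
                                  conditionMessage(e)), "parseError"))
  need <- c("patient", "region", "ig")
  if (nrow(df) == 0L || !all(need %in% names(df)))
    soStop(sprintf("phenotype CSV %s must have columns patient,region,<stains>,ig and at least one row",
                   path), "parseError")
  stains <- setdiff(names(df), need)
  for (s in stains) {
    bad <- which(!(df[[s]] %in% markerVocabulary))
    if (length(bad))
      soStop(sprintf("invalid marker call '%s' at row %d, column %s",
                     df[[s]][bad[1]], bad[1], s), "parseError")
  }
  bad <- which(!(df$ig %in% igVocabulary))
  if (length(bad))
    soStop(sprintf("invalid ig code '%s' at row %d, column ig",
                   df$ig[bad[1]], bad[1]), "parseError")
  new("PhenotypeTable", data = df, stains = stains)
}

#' Classify an Ig light chain code
#'
#' \code{"K"} is kappa-only restriction, \code{"L"} lambda-only; any code
#' with a parenthesised second chain (e.g. \code{"L (K)"}) records
#' co-expression of both light chains and is classified dual.
#'
#' @param code one of \code{"K"}, \code{"L"}, \code{"K (L)"}, \code{"L (K)"},
#'   \code{"unavailable"}.
#' @return One of \code{"kappa_only"}, \code{"lambda_only"}, \code{"dual"},
#'   \code{"unavailable"}.
#' @export
classifyIg <- function(code) {
  if (!(code %in% igVocabulary))
    soStop(sprintf("unknown ig code '%s'", code), "parseError")
  if (code == "unavailable") return("unavailable")
  if (grepl("\\(", code)) return("dual")
  if (code == "K") "kappa_only" else "lambda_only"
}

#' Per-cohort summary counts
#'
#' @slot perStain list: for each stain, a named integer vector of call counts
#'   over the closed vocabulary.
#' @slot igCounts named integer: kappa_only, lambda_only, dual, unavailable.
#' @slot eberPositive integer: xenografts with EBER "+".
#' @slot evaluable integer: rows with histology available.
#' @slot nRows integer: total rows.
#' @export
setClass("SummaryCounts", representation(perStain = "list",
                                         igCounts = "integer",
                                         eberPositive = "integer",
                                         evaluable = "integer",
                                         nRows = "integer"))

setMethod("show", "SummaryCounts", function(object) {
  cat(sprintf("SummaryCounts: %d xenografts (%d evaluable)\n",
              object@nRows, object@evaluable))
  cat(sprintf("  Ig: %d kappa-only, %d lambda-only, %d dual, %d unavailable\n",
              object@igCounts["kappa_only"], object@igCounts["lambda_only"],
              object@igCounts["dual"], object@igCounts["unavailable"]))
  cat(sprintf("  EBER positive: %d/%d\n", object@eberPositive, object@evaluable))
})

#' @rdname SummaryCounts-class
#' @param counts a \code{SummaryCounts}.
#' @export
igCounts <- function(counts) counts@igCounts
#' @rdname SummaryCounts-class
#' @export
perStainCounts <- function(counts) counts@perStain
#' @rdname SummaryCounts-class
#' @export
eberPositive <- function(counts) counts@eberPositive
#' @rdname SummaryCounts-class
#' @export
evaluableRows <- function(counts) counts@evaluable

#' Summarise a phenotype table
#'
#' Counts every marker call per stain, classifies Ig light chain codes, and
#' counts EBER-positive xenografts. Evaluable means histology was available:
#' total rows minus fully "unavailable" rows.
#'
#' @param table a \linkS4class{PhenotypeTable}.
#' @return A \linkS4class{SummaryCounts}.
#' @export
countCategories <- function(table) {
  df <- table@data
  perStain <- lapply(table@stains, function(s) {
    v <- vapply(markerVocabulary, function(call) sum(df[[s]] == call), 0L)
    names(v) <- markerVocabulary
    v
  })
  names(perStain) <- table@stains
  igc <- c(kappa_only = 0L, lambda_only = 0L, dual = 0L, unavailable = 0L)
  for (code in df$ig) {
    cl <- classifyIg(code)
    igc[cl] <- igc[cl] + 1L
  }
  unavailableRows <- if (nrow(df) == 0L) 0L else
    sum(apply(df[, c(table@stains, "ig"), drop = FALSE], 1,
              function(r) all(r == "unavailable")))
  eber <- if ("EBER" %in% table@stains) sum(df$EBER == "+") else 0L
  new("SummaryCounts", perStain = perStain, igCounts = igc,
      eberPositive = as.integer(eber),
      evaluable = as.integer(nrow(df) - unavailableRows),
      nRows = nrow(df))
}

#' Format a proportion as a percentage with one decimal
#'
#' Rounds half away from zero (so 8.85 prints as "8.9%", matching how
#' clinical counts are conventionally reported), one decimal place.
#'
#' @param k numerator count, 0 <= k <= n.
#' @param n denominator count, > 0.
#' @return Character like "11.0\%".
#' @examples
#' proportionPct(16, 145)  # "11.0%"
#' proportionPct(6, 68)    # "8.8%"
#' @export
proportionPct <- function(k, n) {
  if (n <= 0) soStop("denominator must be > 0", "parameterError")
  if (k < 0 || k > n) soStop("need 0 <= k <= n", "parameterError")
  pct <- floor(100 * k / n * 10 + 0.5) / 10
  sprintf("%.1f%%", pct)
}

#' Result of a two-group statistical comparison
#'
#' @slot statistic numeric >= 0.
#' @slot pValue numeric in [0, 1].
#' @slot significantAt005 logical, TRUE iff p < 0.05.
#' @slot method character description.
#' @export
setClass("TestResult", representation(statistic = "numeric",
                                      pValue = "numeric",
                                      significantAt005 = "logical",
                                      method = "character"),
         validity = function(object) {
           if (object@pValue < 0 || object@pValue > 1)
             return("p-value must lie in [0, 1]")
           if (object@significantAt005 != (object@pValue < 0.05))
             return("significance flag inconsistent with p-value")
           TRUE
         })

setMethod("show", "TestResult", function(object) {
  cat(sprintf("%s\n  statistic = %.4f, p = %.4f (%s at 0.05)\n",
              object@method, object@statistic, object@pValue,
              if (object@significantAt005) "significant" else "ns"))
})

#' @rdname TestResult-class
#' @param result a \code{TestResult}.
#' @export
testStatistic <- function(result) result@statistic
#' @rdname TestResult-class
#' @export
testPValue <- function(result) result@pValue
#' @rdname TestResult-class
#' @export
isSignificantAt005 <- function(result) result@significantAt005

#' Pearson chi-square test of two proportions
#'
#' Pearson chi-square on the 2x2 table [[k1, n1 - k1], [k2, n2 - k2]],
#' without continuity correction, df = 1, two-sided, alpha 0.05 — the
#' plainest form of the test.
#'
#' @param k1,n1 successes and total in group 1.
#' @param k2,n2 successes and total in group 2.
#' @return A \linkS4class{TestResult}.
#' @examples
#' twoProportionChi2(8, 45, 6, 60)    # LUAD vs LUSC rates: ns
#' twoProportionChi2(6, 68, 10, 77)   # fresh vs cryopreserved: ns
#' @export
twoProportionChi2 <- function(k1, n1, k2, n2) {
  if (any(c(k1, k2) < 0) || k1 > n1 || k2 > n2 || n1 < 1 || n2 < 1)
    soStop("counts must satisfy 0 <= k <= n, n >= 1", "parameterError")
  tab <- matrix(c(k1, n1 - k1, k2, n2 - k2), 2L, 2L, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    soStop("degenerate 2x2 table: a margin is zero", "degenerateTableError")
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected <= 0))
    soStop("degenerate 2x2 table: zero expected cell", "degenerateTableError")
  res <- stats::chisq.test(tab, correct = FALSE)
  p <- as.numeric(res$p.value)
  new("TestResult", statistic = as.numeric(res$statistic), pValue = p,
      significantAt005 = p < 0.05,
      method = "Pearson chi-square, 2x2, no continuity correction")
}

#' Rank-sum comparison of days-to-event between two groups
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) on user-supplied per-sample day
#' vectors, e.g. injection-to-detection latency of lymphoproliferations vs
#' NSCLC xenografts. No bundled fixture: per-sample values are the user's.
#'
#' @param daysA,daysB numeric vectors of per-sample days.
#' @return A \linkS4class{TestResult}.
#' @export
compareLatencyDays <- function(daysA, daysB) {
  res <- stats::wilcox.test(daysA, daysB, alternative = "two.sided",
                            exact = FALSE)
  p <- as.numeric(res$p.value)
  new("TestResult", statistic = as.numeric(res$statistic), pValue = p,
      significantAt005 = p < 0.05,
      method = "Mann-Whitney rank-sum, two-sided")
}

#' Kruskal-Wallis comparison of days-to-event across groups
#'
#' @param groups named list of numeric per-sample day vectors.
#' @return A \linkS4class{TestResult}.
#' @export
compareHarvestDays <- function(groups) {
  res <- stats::kruskal.test(groups)
  p <- as.numeric(res$p.value)
  new("TestResult", statistic = as.numeric(res$statistic), pValue = p,
      significantAt005 = p < 0.05, method = "Kruskal-Wallis rank-sum")
}

#' Write a cohort summary JSON
#'
#' Aggregates \code{\link{countCategories}} output plus formatted proportions
#' and (optionally) a two-proportion chi-square into a machine-readable
#' summary file.
#'
#' @param table a \linkS4class{PhenotypeTable}.
#' @param path output JSON path.
#' @param comparisons optional named list of count quadruplets
#'   \code{c(k1, n1, k2, n2)} to test with \code{\link{twoProportionChi2}}.
#' @return The summary list, invisibly.
#' @export
writeCohortSummary <- function(table, path, comparisons = list()) {
  cc <- countCategories(table)
  tests <- lapply(comparisons, function(q) {
    r <- twoProportionChi2(q[1], q[2], q[3], q[4])
    list(counts = as.integer(q), statistic = r@statistic, p_value = r@pValue,
         significant_at_0_05 = r@significantAt005, method = r@method)
  })
  out <- list(
    n_rows = cc@nRows,
    evaluable = cc@evaluable,
    per_stain = lapply(cc@perStain, as.list),
    ig_counts = as.list(cc@igCounts),
    ig_kappa_only_pct = proportionPct(cc@igCounts[["kappa_only"]], cc@evaluable),
    eber_positive = cc@eberPositive,
    eber_positive_pct = proportionPct(cc@eberPositive, cc@evaluable),
    tests = tests)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(out)
}
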