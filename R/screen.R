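#' Log2 area under a bacterial growth curve
#'
#' Growth is quantified as the trapezoidal integral of optical density over
#' time (OD x hours), log2 transformed. No smoothing is applied: the
#' integral is taken on the observed grid.
#'
#' @param times strictly increasing measurement times in hours (>= 2).
#' @param od optical density readings (same length, >= 0).
#' @return the log2 AUC, in log2(OD x h).
#' @export
#' @examples
#' growth_auc(c(0, 18), c(0.5, 0.5))  # rectangle: log2(9)
growth_auc <- function(times, od) {
  if (length(times) < 2 || length(times) != length(od)) {
    stop("need >= 2 paired time/OD observations")
  }
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  auc <- sum(diff(times) * (head(od, -1) + tail(od, -1)) / 2)
  if (auc <= 0) stop("AUC must be positive (apply an OD floor upstream)")
  log2(auc)
}

#' Robust per-worm fluorescence summary (Q90)
#'
#' The 90th percentile of the log2-transformed intensity distribution, a
#' robust measure of maximum reporter fluorescence in segmented worms whose
#' intensities span the whole dynamic range. Quantiles use linear
#' interpolation between order statistics.
#'
#' @param values positive intensity values (arbitrary fluorescence units).
#' @param prob quantile level (default 0.9).
#' @return the Q90 statistic on the log2 scale.
#' @export
q90_intensity <- function(values, prob = 0.9) {
  if (!length(values)) stop("empty intensity vector")
  if (any(values <= 0)) stop("intensities must be positive")
  unname(quantile(log2(values), probs = prob, type = 7))
}

#' Drug-by-nutrient interaction linear models across a screen
#'
#' Fits a linear model with nutrient, drug and nutrient-by-drug terms on the
#' log2 responses of the 2x2 design cells of each nutrient (base medium and
#' nutrient, each with and without drug); base-medium wells are shared
#' across nutrients per the plate design. By default one model is fitted to
#' the whole plate (a saturated cell-means model), so the residual variance
#' is pooled across every well of the screen and each nutrient's contrasts
#' are tested against it ("multiple univariate analysis"); with
#' `pool_variance = FALSE` each nutrient gets its own 16-well `lm()` fit
#' instead. The interaction p-values are Benjamini-Hochberg adjusted across
#' nutrients; a significant positive interaction means the nutrient
#' suppresses the drug effect (antagonistic), a significant negative one
#' amplifies it (synergistic).
#'
#' @param design data.frame with columns `nutrient` (NA or "" for
#'   base-medium wells), `drug` (logical), `response` (log2 scale). An
#'   optional `replicate` column is ignored by the fixed-effects fit.
#' @param fdr_threshold FDR below which a call is made (default 0.05).
#' @param pool_variance pool the residual variance across the entire plate
#'   (default) or fit each nutrient separately.
#' @return data.frame, one row per nutrient: main effects and standard
#'   errors (`effect_nutrient`, `se_nutrient`, `effect_drug`, `se_drug`),
#'   `interaction`, `se_interaction`, `p_interaction`, `fdr` and `call`
#'   (antagonistic / synergistic / neutral). Nutrients missing any design
#'   cell are skipped with a warning.
#' @export
fit_interactions <- function(design, fdr_threshold = 0.05,
                             pool_variance = TRUE) {
  nut <- design$nutrient
  nut[is.na(nut)] <- ""
  drug <- as.logical(design$drug)
  y <- design$response
  if (!any(nut == "")) stop("design has no base-medium (nutrient-free) wells")
  nutrients <- sort(unique(nut[nut != ""]))

  cell <- paste0(nut, "\r", drug)
  cn <- tapply(y, cell, length)
  cm <- tapply(y, cell, mean)
  css <- tapply(y, cell, function(v) sum((v - mean(v))^2))
  stat <- function(nu, d) {
    key <- paste0(nu, "\r", d)
    if (is.na(match(key, names(cn)))) c(NA, NA)
    else c(cm[[key]], cn[[key]])
  }
  df_pool <- length(y) - length(cn)
  s2_pool <- if (df_pool > 0) sum(css) / df_pool else 0

  rows <- vector("list", length(nutrients))
  skipped <- character()
  for (i in seq_along(nutrients)) {
    bF <- stat("", FALSE); bT <- stat("", TRUE)
    nF <- stat(nutrients[i], FALSE); nT <- stat(nutrients[i], TRUE)
    if (anyNA(c(bF, bT, nF, nT))) {
      skipped <- c(skipped, nutrients[i])
      next
    }
    if (pool_variance) {
      s2 <- s2_pool; dfree <- df_pool
    } else {
      keys <- paste0(c("", "", nutrients[i], nutrients[i]), "\r",
                     c(FALSE, TRUE, FALSE, TRUE))
      dfree <- sum(cn[keys]) - 4
      s2 <- if (dfree > 0) sum(css[keys]) / dfree else 0
    }
    mkterm <- function(est, wts) {
      se <- sqrt(s2 * wts)
      p <- if (se > 0 && dfree > 0) 2 * pt(-abs(est / se), dfree)
           else as.numeric(abs(est) < 1e-12)
      c(est = est, se = se, p = p)
    }
    nut_t <- mkterm(nF[1] - bF[1], 1 / nF[2] + 1 / bF[2])
    drug_t <- mkterm(bT[1] - bF[1], 1 / bT[2] + 1 / bF[2])
    int_t <- mkterm((nT[1] - nF[1]) - (bT[1] - bF[1]),
                    1 / nT[2] + 1 / nF[2] + 1 / bT[2] + 1 / bF[2])
    rows[[i]] <- data.frame(
      nutrient_id = nutrients[i],
      effect_nutrient = nut_t[["est"]], se_nutrient = nut_t[["se"]],
      effect_drug = drug_t[["est"]], se_drug = drug_t[["se"]],
      interaction = int_t[["est"]], se_interaction = int_t[["se"]],
      p_interaction = int_t[["p"]],
      stringsAsFactors = FALSE)
  }
  if (length(skipped)) {
    warning("nutrient(s) missing a design cell, skipped: ",
            paste(skipped, collapse = ", "))
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no nutrient with a complete 2x2 design")
  out$fdr <- p.adjust(out$p_interaction, method = "BH")
  out$call <- ifelse(out$fdr >= fdr_threshold | is.na(out$fdr), "neutral",
                     ifelse(out$interaction > 0, "antagonistic",
                            "synergistic"))
  out
}

#' Hypergeometric enrichment of metabolite classes among screen hits
#'
#' Upper-tail hypergeometric test per class (probability of drawing at
#' least the observed number of class members among the hits), with
#' Benjamini-Hochberg adjustment across classes.
#'
#' @param hit_set character vector of hits (must be a subset of `universe`).
#' @param universe character vector of all screened items.
#' @param class_map data.frame with columns `item` and `class` (an item may
#'   carry several classes). Classes with no member in the universe are
#'   skipped.
#' @return data.frame: `class`, `k` (class hits), `K` (class size in
#'   universe), `n` (hits), `N` (universe size), `p`, `fdr`.
#' @export
enrich <- function(hit_set, universe, class_map) {
  universe <- unique(universe)
  hit_set <- unique(hit_set)
  if (length(setdiff(hit_set, universe))) {
    stop("hit_set contains items outside the universe: ",
         paste(setdiff(hit_set, universe), collapse = ", "))
  }
  cm <- class_map[class_map$item %in% universe, , drop = FALSE]
  classes <- sort(unique(cm$class))
  N <- length(universe)
  n <- length(hit_set)
  out <- do.call(rbind, lapply(classes, function(cl) {
    members <- unique(cm$item[cm$class == cl])
    K <- length(members)
    k <- length(intersect(members, hit_set))
    data.frame(class = cl, k = k, K = K, n = n, N = N,
               p = phyper(k - 1, K, N - K, n, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  }))
  out$fdr <- p.adjust(out$p, method = "BH")
  out
}

#' Association between predicted production and a screen readout
#'
#' Ordinary least squares of a per-nutrient screen metric (e.g. the
#' drug-context fluorescence fold change) on the predicted production
#' capacity ratio of the same nutrients.
#'
#' @param capacity_ratios named numeric vector, nutrient -> predicted ratio.
#' @param screen_metric named numeric vector, nutrient -> measured metric.
#' @return list: `slope`, `se`, `p`, `intercept`, `n` (paired nutrients).
#' @export
associate_prediction <- function(capacity_ratios, screen_metric) {
  common <- intersect(names(capacity_ratios), names(screen_metric))
  if (length(common) < 3) stop("need >= 3 paired nutrients")
  x <- as.numeric(capacity_ratios[common])
  y <- as.numeric(screen_metric[common])
  if (var(x) == 0) stop("predictor has zero variance")
  fit <- lm(y ~ x)
  cf <- summary(fit)$coefficients
  list(slope = cf["x", 1], se = cf["x", 2], p = cf["x", 4],
       intercept = cf["(Intercept)", 1], n = length(common))
}
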