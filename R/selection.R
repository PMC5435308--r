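#' Covariate catalog
#'
#' Declares the covariates available for screening: each has a unique name
#' and a category (vegetation, climate, topographic, anthropogenic). For a
#' covariate `foo`, the dataset frame may carry columns `foo_250` and
#' `foo_1000` (the two focal scales) or a scale-free column `foo`.
#'
#' @param name character vector of covariate names.
#' @param category matching vector of categories.
#' @return `data.frame` classed `covariate_catalog`.
#' @export
covariate_catalog <- function(name, category) {
  if (anyDuplicated(name)) stop("covariate names must be unique", call. = FALSE)
  ok <- c("vegetation", "climate", "topographic", "anthropogenic")
  if (!all(category %in% ok))
    stop("categories must be one of: ", paste(ok, collapse = ", "),
         call. = FALSE)
  structure(data.frame(name = name, category = category,
                       stringsAsFactors = FALSE),
            class = c("covariate_catalog", "data.frame"))
}

.cov_columns <- function(name, frame) {
  cand <- paste0(name, c("_250", "_1000"))
  present <- cand[cand %in% names(frame)]
  if (length(present) == 0 && name %in% names(frame)) present <- name
  present
}

#' Univariate covariate screening
#'
#' Step one of the two-step selection: each covariate is tried at each
#' available focal scale as the single predictor on one side of the model
#' (the other side held at its base structure: `~ occasion` for abundance,
#' `~ 1` for detection), and compared by AICc to the null model. Abundance
#' retains every covariate whose best-scale AICc is less than or equal to
#' the null's; detection retains only the single best-performing covariate.
#' Exact scale ties resolve to the 1000-m scale. Covariates whose fits fail
#' are skipped with a warning.
#'
#' @param data an [make_hds_data()] object.
#' @param catalog a [covariate_catalog].
#' @param side `"abundance"` or `"detection"`.
#' @param family detection family passed to [fit_hds()].
#' @param base_abundance abundance structure held fixed (default
#'   `~ occasion`).
#' @return `data.frame` of retained covariates (`name`, `category`,
#'   `column`, `AICc`) sorted by AICc, with attribute `null_aicc`.
#' @export
screen_univariate <- function(data, catalog, side = c("abundance", "detection"),
                              family = "halfnorm",
                              base_abundance = ~occasion) {
  side <- match.arg(side)
  stopifnot(inherits(catalog, "covariate_catalog"))
  null_fit <- fit_hds(data, base_abundance, ~1, family)
  rows <- list()
  for (i in seq_len(nrow(catalog))) {
    nm <- catalog$name[i]
    cols <- .cov_columns(nm, data$frame)
    if (length(cols) == 0) {
      warning(sprintf("covariate '%s' has no column in the data; skipped", nm))
      next
    }
    best <- NULL
    for (cl in cols) {
      if (stats::sd(data$frame[[cl]]) == 0) {
        warning(sprintf("covariate column '%s' is constant; skipped", cl))
        next
      }
      ab <- if (side == "abundance")
        stats::update.formula(base_abundance, paste("~ . +", cl))
        else base_abundance
      dt <- if (side == "detection") stats::as.formula(paste("~", cl)) else ~1
      f <- tryCatch(fit_hds(data, ab, dt, family), error = function(e) NULL)
      if (is.null(f)) {
        warning(sprintf("univariate fit failed for '%s'; skipped", cl))
        next
      }
      # >= so an exact tie prefers the 1000-m scale (tried second)
      if (is.null(best) || best$AICc >= f$AICc)
        best <- list(column = cl, AICc = f$AICc)
    }
    if (!is.null(best))
      rows[[length(rows) + 1L]] <- data.frame(
        name = nm, category = catalog$category[i], column = best$column,
        AICc = best$AICc, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(name = character(), category = character(),
               column = character(), AICc = numeric())
  out <- out[order(out$AICc), , drop = FALSE]
  if (side == "abundance") {
    # the better-than-or-equal-to-null gate applies to the abundance side
    out <- out[out$AICc <= null_fit$AICc, , drop = FALSE]
  } else if (nrow(out) > 1) {
    out <- out[1, , drop = FALSE]
  }
  rownames(out) <- NULL
  attr(out, "null_aicc") <- null_fit$AICc
  out
}

#' Prune pairwise-correlated covariates
#'
#' For every covariate pair with Pearson `|r|` above the threshold, the
#' member with the higher univariate AICc is dropped. Applied greedily in
#' ascending AICc order so the best-supported covariate always survives.
#' Constant covariates (undefined r) are excluded with a warning.
#'
#' @param screened output of [screen_univariate()] (abundance side).
#' @param data the dataset (columns read from `data$frame`).
#' @param threshold correlation magnitude above which a pair conflicts
#'   (default 0.7).
#' @return The pruned screening `data.frame`.
#' @export
prune_correlated <- function(screened, data, threshold = 0.7) {
  if (nrow(screened) <= 1) return(screened)
  ok <- vapply(screened$column,
               function(cl) stats::sd(data$frame[[cl]]) > 0, logical(1))
  if (any(!ok)) {
    warning("dropping constant covariate(s): ",
            paste(screened$column[!ok], collapse = ", "))
    screened <- screened[ok, , drop = FALSE]
  }
  scr <- screened[order(screened$AICc), , drop = FALSE]
  kept <- integer(0)
  for (i in seq_len(nrow(scr))) {
    xi <- data$frame[[scr$column[i]]]
    conflict <- any(vapply(kept, function(k)
      abs(stats::cor(xi, data$frame[[scr$column[k]]])) > threshold,
      logical(1)))
    if (!conflict) kept <- c(kept, i)
  }
  out <- scr[kept, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Variance inflation factors with iterative pruning
#'
#' `VIF_k = 1/(1 - R^2_k)` from regressing column k on the remaining
#' columns (with intercept). Columns are removed one at a time, highest
#' VIF first, until all remaining VIFs are at or below the threshold.
#' Exactly collinear columns are removed first via a rank check.
#'
#' @param M numeric matrix or data.frame of covariate columns (no
#'   intercept), more rows than columns.
#' @param threshold maximum acceptable VIF (default 4).
#' @return list with `vif` (named VIFs of the initial, full set after
#'   collinearity repair) and `keep` (names of the surviving columns).
#' @export
check_vif <- function(M, threshold = 4) {
  M <- as.matrix(as.data.frame(M))
  if (ncol(M) < 2) return(list(vif = stats::setNames(rep(1, ncol(M)),
                                                     colnames(M)),
                               keep = colnames(M)))
  if (nrow(M) <= ncol(M))
    stop("need more rows than covariates for VIF", call. = FALSE)
  # drop exactly collinear columns first
  q <- qr(cbind(1, M))
  if (q$rank < ncol(M) + 1) {
    drop_idx <- q$pivot[-seq_len(q$rank)] - 1L
    drop_idx <- drop_idx[drop_idx >= 1]
    warning("removing exactly collinear column(s): ",
            paste(colnames(M)[drop_idx], collapse = ", "))
    M <- M[, -drop_idx, drop = FALSE]
  }
  vif_of <- function(A) {
    vapply(seq_len(ncol(A)), function(k) {
      fit <- stats::lm.fit(cbind(1, A[, -k, drop = FALSE]), A[, k])
      r2 <- 1 - sum(fit$residuals^2) / sum((A[, k] - mean(A[, k]))^2)
      1 / (1 - min(r2, 1 - 1e-12))
    }, numeric(1))
  }
  full_vif <- stats::setNames(vif_of(M), colnames(M))
  A <- M
  while (ncol(A) >= 2) {
    v <- vif_of(A)
    if (max(v) <= threshold) break
    A <- A[, -which.max(v), drop = FALSE]
  }
  list(vif = full_vif, keep = colnames(A))
}

#' Build the candidate model set
#'
#' Emits the fixed candidate grammar: for abundance a null
#' (occasion-only), a global model with every surviving covariate, one
#' model per covariate category, and a "top mix" with the single
#' best-supported covariate from each category; every abundance candidate
#' includes the occasion factor. For detection: the top covariate as a
#' continuous term, as a 3-level equal-width categorical (cut on the
#' sampled min/max), occasion-only, and occasion plus the categorical.
#' Categories with no surviving covariate collapse to occasion-only and
#' are flagged; structurally identical candidates are collapsed (first
#' name wins).
#'
#' @param pruned abundance screening table after [prune_correlated()] /
#'   [check_vif()].
#' @param detection_cov optional single-row detection screening table (or
#'   `NULL` for occasion-only detection candidates).
#' @param data the dataset; returned augmented with the categorical
#'   detection column when one is created.
#' @return list with `abundance` (named list of formulas), `detection`
#'   (named list of formulas), `data` (possibly augmented), and
#'   `collapsed` (names of empty-category candidates dropped).
#' @export
build_candidates <- function(pruned, detection_cov = NULL, data) {
  cats <- c(Vegetation = "vegetation", Topography = "topographic",
            Climate = "climate", Anthropogenic = "anthropogenic")
  mk <- function(cols) {
    if (length(cols) == 0) return(~occasion)
    stats::as.formula(paste("~", paste(c(cols, "occasion"), collapse = " + ")))
  }
  ab <- list(Global = mk(pruned$column))
  collapsed <- character(0)
  for (i in seq_along(cats)) {
    cols <- pruned$column[pruned$category == cats[i]]
    if (length(cols) == 0) collapsed <- c(collapsed, names(cats)[i])
    ab[[names(cats)[i]]] <- mk(cols)
  }
  top_mix <- vapply(cats, function(cc) {
    cols <- pruned$column[pruned$category == cc]
    if (length(cols) == 0) NA_character_ else cols[1]  # pruned is AICc-sorted
  }, character(1))
  ab$`Top Mix` <- mk(top_mix[!is.na(top_mix)])
  ab$Null <- ~occasion
  # collapse structurally identical candidates, keeping the first name
  sig <- vapply(ab, function(f) paste(sort(all.vars(f)), collapse = "+"),
                character(1))
  ab <- ab[!duplicated(sig)]
  det <- list()
  if (!is.null(detection_cov) && nrow(detection_cov) >= 1) {
    cl <- detection_cov$column[1]
    x <- data$frame[[cl]]
    br <- seq(min(x), max(x), length.out = 4L)
    catname <- paste0(cl, "_cat")
    data$frame[[catname]] <- cut(x, breaks = br, include.lowest = TRUE,
                                 labels = c("L", "M", "H"))
    det[[paste0(cl, " continuous")]] <- stats::as.formula(paste("~", cl))
    det[[paste0(cl, " category")]] <- stats::as.formula(paste("~", catname))
    det[["Occasion"]] <- ~occasion
    det[[paste0("Occasion + ", cl, " category")]] <-
      stats::as.formula(paste("~ occasion +", catname))
    # a 3-level cut can be rank-deficient on sparse data; drop empty levels
    if (any(table(data$frame[[catname]]) == 0)) {
      det[[paste0(cl, " category")]] <- NULL
      det[[paste0("Occasion + ", cl, " category")]] <- NULL
    }
  } else {
    det[["Occasion"]] <- ~occasion
    det[["Null"]] <- ~1
  }
  list(abundance = ab, detection = det, data = data, collapsed = collapsed)
}

# Rank a named list of fitted models into a selection table.
selection_table <- function(fits, c_hat = NULL) {
  ok <- !vapply(fits, is.null, logical(1))
  fits <- fits[ok]
  crit <- vapply(fits, function(f) {
    if (!is.null(c_hat) && c_hat > 1) qaic_c(f$logLik, f$K, f$n, c_hat)
    else f$AICc
  }, numeric(1))
  ord <- order(crit)
  tab <- data.frame(
    Model = names(fits)[ord],
    K = vapply(fits, `[[`, 0L, "K")[ord],
    AICc = crit[ord],
    Delta = crit[ord] - min(crit),
    LL = vapply(fits, `[[`, 0, "logLik")[ord],
    row.names = NULL)
  wt <- exp(-tab$Delta / 2)
  tab$Weight <- wt / sum(wt)
  tab <- tab[c("Model", "K", "AICc", "Delta", "Weight", "LL")]
  class(tab) <- c("selection_table", "data.frame")
  tab
}

#' @export
print.selection_table <- function(x, ...) {
  y <- as.data.frame(x)
  y$AICc <- round(y$AICc, 2); y$Delta <- round(y$Delta, 2)
  y$Weight <- round(y$Weight, 3); y$LL <- round(y$LL, 2)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Write a selection table as CSV
#'
#' Columns: Model, K, AICc, Delta_AICc, AICc_Wt, LL.
#' @param tab a selection table.
#' @param path output CSV path.
#' @export
write_selection_table <- function(tab, path) {
  out <- as.data.frame(tab)
  names(out) <- c("Model", "K", "AICc", "Delta_AICc", "AICc_Wt", "LL")
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Three-phase candidate-set selection
#'
#' Phase 1 ranks the detection candidates while abundance is held at
#' occasion-only; phase 2 ranks the abundance candidates under the winning
#' detection structure; phase 3 re-runs the winning abundance structure
#' against every detection candidate to confirm (or revise) the detection
#' choice. Ranking uses AICc, or QAICc throughout when an over-dispersion
#' factor `c_hat > 1` is supplied. Candidates whose fits fail are excluded
#' from their table with a warning.
#'
#' @param data dataset (use `candidates$data`, which may carry the
#'   categorical detection column).
#' @param candidates output of [build_candidates()].
#' @param family detection family.
#' @param c_hat optional over-dispersion factor (switches to QAICc).
#' @return list with `fit` (the final model), `detection_table`,
#'   `abundance_table`, `detection_recheck_table`, and the winning formula
#'   names.
#' @export
select_models <- function(data, candidates, family = "halfnorm",
                          c_hat = NULL) {
  fit_or_null <- function(ab, dt) {
    tryCatch(fit_hds(data, ab, dt, family),
             error = function(e) { warning(conditionMessage(e)); NULL })
  }
  # phase 1: detection contest under occasion-only abundance
  det_fits <- lapply(candidates$detection, function(dt)
    fit_or_null(~occasion, dt))
  det_tab <- selection_table(det_fits, c_hat)
  best_det <- candidates$detection[[det_tab$Model[1]]]
  # phase 2: abundance contest under the winning detection structure
  ab_fits <- lapply(candidates$abundance, function(ab)
    fit_or_null(ab, best_det))
  ab_tab <- selection_table(ab_fits, c_hat)
  best_ab_name <- ab_tab$Model[1]
  best_ab <- candidates$abundance[[best_ab_name]]
  # phase 3: re-verify detection under the winning abundance structure
  det_fits2 <- lapply(candidates$detection, function(dt)
    fit_or_null(best_ab, dt))
  det_tab2 <- selection_table(det_fits2, c_hat)
  final_det_name <- det_tab2$Model[1]
  final <- det_fits2[[final_det_name]]
  list(fit = final,
       detection_table = det_tab, abundance_table = ab_tab,
       detection_recheck_table = det_tab2,
       abundance_model = best_ab_name, detection_model = final_det_name)
}
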