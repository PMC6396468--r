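#' Module delta scores for a variant-exon pair
#'
#' Scores the five region sub-sequences of the reference and the alternative
#' allele with the trained modules and returns the five score differences
#' `dS = S_alt - S_ref`, together with three binary indicators marking
#' variants that fall inside a doubly-scored window: the exonic splice-site
#' windows (last 5 / first 3 exonic nt) for the exon module, the 13 intronic
#' donor-window nt for the 5' intron module, and the 50 intronic
#' acceptor-window nt for the 3' intron module. Indicators are computed on
#' the variant's REF interval (an insertion occupies its anchor base).
#'
#' @param pair An `ss_pair` from [apply_variant()].
#' @param modules Named list of six trained `ss_module`s (see
#'   [build_module_set()]).
#' @param exon_head Which exon module scores the exon segment: `"exon5p"`
#'   (default; the better exon-skipping predictor) or `"exon3p"`.
#' @param windows A [window_spec()].
#' @return One-row data frame with `dS_intron3p`, `dS_acceptor`, `dS_exon`,
#'   `dS_donor`, `dS_intron5p`, `ind_exon_ss`, `ind_intron5p_donor`,
#'   `ind_intron3p_acceptor`.
#' @export
module_delta_scores <- function(pair, modules, exon_head = c("exon5p", "exon3p"),
                                windows = window_spec()) {
  stopifnot(inherits(pair, "ss_pair"))
  exon_head <- match.arg(exon_head)
  need <- c("donor", "acceptor", "intron5p", "intron3p", exon_head)
  missing <- setdiff(need, names(modules))
  if (length(missing)) stop("missing module(s): ", paste(missing, collapse = ", "))
  if (!all(vapply(modules[need], function(m) isTRUE(m$trained), logical(1)))) {
    stop("all modules must be trained before scoring")
  }
  ref <- split_region(pair$ref_region, windows)
  alt <- split_region(pair$alt_region, windows)
  ds <- function(mod, r, a) score_sequence(mod, a) - score_sequence(mod, r)
  iv <- variant_interval(pair$variant)
  w <- indicator_windows(pair$exon, windows)
  data.frame(
    dS_intron3p = ds(modules$intron3p, ref$intron3p, alt$intron3p),
    dS_acceptor = ds(modules$acceptor, ref$acceptor, alt$acceptor),
    dS_exon     = ds(modules[[exon_head]], ref$exon, alt$exon),
    dS_donor    = ds(modules$donor, ref$donor, alt$donor),
    dS_intron5p = ds(modules$intron5p, ref$intron5p, alt$intron5p),
    ind_exon_ss = as.integer(intervals_intersect(iv, w$donor_exonic) ||
                             intervals_intersect(iv, w$acceptor_exonic)),
    ind_intron5p_donor = as.integer(intervals_intersect(iv, w$donor_intronic)),
    ind_intron3p_acceptor = as.integer(intervals_intersect(iv, w$acceptor_intronic))
  )
}

delta_feature_names <- function() {
  c("dS_intron3p", "dS_acceptor", "dS_exon", "dS_donor", "dS_intron5p",
    "ind_exon_ss", "ind_intron5p_donor", "ind_intron3p_acceptor")
}

# Design matrix of the nine-parameter linear composition model:
# intercept, five dS terms, and the three indicator-by-dS interactions that
# prevent double counting of variants scored by two modules.
effect_design_matrix <- function(scores) {
  miss <- setdiff(delta_feature_names(), names(scores))
  if (length(miss)) stop("missing feature column(s): ", paste(miss, collapse = ", "))
  X <- cbind(
    intercept = 1,
    dS_intron3p = scores$dS_intron3p,
    dS_acceptor = scores$dS_acceptor,
    dS_exon = scores$dS_exon,
    dS_donor = scores$dS_donor,
    dS_intron5p = scores$dS_intron5p,
    ind_exon_ss.dS_exon = scores$ind_exon_ss * scores$dS_exon,
    ind_intron5p_donor.dS_intron5p = scores$ind_intron5p_donor * scores$dS_intron5p,
    ind_intron3p_acceptor.dS_intron3p = scores$ind_intron3p_acceptor * scores$dS_intron3p
  )
  if (any(!is.finite(X))) stop("non-finite feature values")
  X
}

huber_loss <- function(r, delta) {
  a <- abs(r)
  ifelse(a <= delta, 0.5 * r^2, delta * (a - 0.5 * delta))
}

#' Fit a linear composition model with Huber loss
#'
#' Fits the nine-parameter linear model (intercept + five module deltas +
#' three indicator interactions) to a continuous response — delta-logit(PSI)
#' for exon skipping, or the allelic log-ratio for splicing efficiency — by
#' minimising the Huber loss, which keeps the fit robust to the gross
#' outliers typical of reporter measurements. Module weights are never
#' touched by this fit. Optimisation is BFGS with the analytic gradient,
#' started at the least-squares solution.
#'
#' @param rows Data frame holding the eight feature columns of
#'   [module_delta_scores()] plus a `response` column.
#' @param purpose One of `"delta_logit_psi"`,
#'   `"splicing_efficiency_invivo"`, `"splicing_efficiency_invitro"`.
#' @param huber_delta Transition point of the Huber loss (default 1.0).
#' @param response Optional response column name (default `"response"`).
#' @return An `ss_effect_model` with the nine named coefficients.
#' @export
fit_effect_model <- function(rows, purpose = c("delta_logit_psi",
                                               "splicing_efficiency_invivo",
                                               "splicing_efficiency_invitro"),
                             huber_delta = 1.0, response = "response") {
  purpose <- match.arg(purpose)
  stopifnot(huber_delta > 0)
  if (!response %in% names(rows)) stop("missing response column: ", response)
  y <- rows[[response]]
  if (any(!is.finite(y))) stop("non-finite response values")
  X <- effect_design_matrix(rows)
  p <- ncol(X)
  if (nrow(X) < p) {
    stop(sprintf("need at least %d rows to fit %d parameters, got %d",
                 p, p, nrow(X)))
  }
  sds <- apply(X[, -1, drop = FALSE], 2, stats::sd)
  if (any(sds == 0)) {
    warning("zero-variance feature column(s): ",
            paste(names(sds)[sds == 0], collapse = ", "))
  }
  beta0 <- stats::coef(stats::lm.fit(X, y))
  beta0[is.na(beta0)] <- 0
  obj <- function(b) sum(huber_loss(y - X %*% b, huber_delta))
  grad <- function(b) {
    r <- as.vector(y - X %*% b)
    psi <- ifelse(abs(r) <= huber_delta, r, huber_delta * sign(r))
    -as.vector(crossprod(X, psi))
  }
  opt <- stats::optim(beta0, obj, grad, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  coefs <- stats::setNames(as.vector(opt$par), colnames(X))
  structure(list(purpose = purpose, coef = coefs, huber_delta = huber_delta,
                 fit = list(loss = opt$value, n = nrow(X),
                            converged = opt$convergence == 0)),
            class = "ss_effect_model")
}

#' @export
print.ss_effect_model <- function(x, ...) {
  cat(sprintf("<ss_effect_model> purpose=%s, %d coefficients (n=%d)\n",
              x$purpose, length(x$coef), x$fit$n))
  print(round(x$coef, 4))
  invisible(x)
}

#' Predict the composition model's delta-logit response
#'
#' @param model An `ss_effect_model`.
#' @param scores Data frame of feature columns (one row per variant-exon
#'   pair).
#' @return Numeric vector of linear predictions (delta-logit(PSI) or allelic
#'   log-ratio, depending on the model's purpose).
#' @export
predict_effect <- function(model, scores) {
  stopifnot(inherits(model, "ss_effect_model"))
  as.vector(effect_design_matrix(scores) %*% model$coef)
}

#' Transform delta-logit(PSI) to delta-PSI
#'
#' `psi_alt = sigmoid(delta_logit + logit(psi_ref))`, `delta_psi = psi_alt -
#' psi_ref`, with `psi_ref` clipped to `[1e-5, 1 - 1e-5]` inside the logit so
#' boundary values stay finite.
#'
#' @param delta_logit Numeric vector of delta-logit(PSI) predictions (or an
#'   `ss_effect_model`, in which case `scores` must be supplied).
#' @param psi_ref Reference PSI values in \[0, 1\] (required; there is no
#'   default reference level).
#' @param scores Feature rows, only when `delta_logit` is a model.
#' @return Data frame with `delta_logit_psi`, `psi_alt`, `delta_psi`.
#' @export
predict_delta_psi <- function(delta_logit, psi_ref, scores = NULL) {
  if (inherits(delta_logit, "ss_effect_model")) {
    if (is.null(scores)) stop("supply feature rows to predict from a model")
    delta_logit <- predict_effect(delta_logit, scores)
  }
  if (missing(psi_ref) || is.null(psi_ref)) {
    stop("psi_ref must be supplied; no default reference PSI is assumed")
  }
  stopifnot(is.numeric(delta_logit))
  psi_alt <- sigmoid(delta_logit + logit_clipped(psi_ref))
  data.frame(delta_logit_psi = delta_logit, psi_alt = psi_alt,
             delta_psi = psi_alt - psi_ref)
}

#' Competing splice-site usage change (delta-PSI5 / delta-PSI3)
#'
#' For a donor with two competing acceptors (or an acceptor with two
#' competing donors), the two exon-level delta-logit predictions `dlogit1`
#' and `dlogit2` combine as `delta_logit(PSI5) = dlogit1 - dlogit2`; the
#' alternative usage is `sigmoid(delta_logit(PSI5) + logit(psi_ref))`.
#' Heterozygous genotypes assume equal expression of the two alleles, so the
#' heterozygous effect is exactly half the homozygous one.
#'
#' @param dlogit1,dlogit2 Delta-logit(PSI) predictions for the two competing
#'   exons.
#' @param psi_ref Reference PSI5 (or PSI3) in \[0, 1\].
#' @param genotype `"hom_alt"` or `"het"`.
#' @return Numeric vector of delta-PSI5 (identical machinery serves
#'   delta-PSI3).
#' @export
predict_competition <- function(dlogit1, dlogit2, psi_ref,
                                genotype = c("hom_alt", "het")) {
  genotype <- match.arg(genotype)
  d <- dlogit1 - dlogit2
  psi_alt <- sigmoid(d + logit_clipped(psi_ref))
  hom <- psi_alt - psi_ref
  if (genotype == "hom_alt") hom else hom / 2
}

#' Allelic log-ratio of splicing efficiency
#'
#' `log2((m_o / m_i) / (w_o / w_i))` where `m_o`/`m_i` are mutant spliced /
#' input read counts and `w_o`/`w_i` the wild-type counterparts.
#' Antisymmetric under swapping mutant and wild type.
#'
#' @param m_o,m_i,w_o,w_i Read counts (> 0 unless a pseudocount is used).
#' @param pseudocount Added to every count; default 0 (zero counts are then
#'   an error).
#' @return Numeric vector.
#' @export
allelic_log_ratio <- function(m_o, m_i, w_o, w_i, pseudocount = 0) {
  counts <- cbind(m_o, m_i, w_o, w_i) + pseudocount
  if (any(counts <= 0)) {
    stop("read counts must be positive (or enable a pseudocount)")
  }
  as.vector(log2((counts[, 1] / counts[, 2]) / (counts[, 3] / counts[, 4])))
}

#' Fit and apply the pathogenicity model
#'
#' Logistic regression classifying pathogenic vs benign variants from the
#' five module delta scores plus the three overlap indicators (feature set
#' `"delta"`, nine weights including the intercept). The extended feature
#' set `"delta_ref"` additionally includes the five reference-allele scores
#' (`S_ref_*` columns). Callers are expected to pre-filter variants to
#' splice-region windows and to drop premature-stop variants via their own
#' predicate.
#'
#' @param rows Data frame with the feature columns and a `label` column
#'   (0 = benign, 1 = pathogenic).
#' @param feature_set `"delta"` (default) or `"delta_ref"`.
#' @return An `ss_effect_model` with purpose `"pathogenicity"`.
#' @export
fit_pathogenicity <- function(rows, feature_set = c("delta", "delta_ref")) {
  feature_set <- match.arg(feature_set)
  y <- rows$label
  if (is.null(y) || length(unique(y)) < 2L) {
    stop("need both benign and pathogenic examples")
  }
  feats <- pathogenicity_features(feature_set)
  miss <- setdiff(feats, names(rows))
  if (length(miss)) stop("missing feature column(s): ", paste(miss, collapse = ", "))
  d <- rows[, c(feats, "label")]
  fit <- stats::glm(label ~ ., data = d, family = stats::binomial())
  structure(list(purpose = "pathogenicity", feature_set = feature_set,
                 coef = stats::coef(fit), glm = fit,
                 fit = list(n = nrow(d), deviance = fit$deviance)),
            class = "ss_effect_model")
}

pathogenicity_features <- function(feature_set) {
  base <- delta_feature_names()
  if (feature_set == "delta_ref") {
    c(base, paste0("S_ref_", c("intron3p", "acceptor", "exon", "donor", "intron5p")))
  } else base
}

#' @rdname fit_pathogenicity
#' @param model Fitted pathogenicity `ss_effect_model`.
#' @param features Data frame of feature rows.
#' @return `predict_pathogenicity` returns probabilities in (0, 1).
#' @export
predict_pathogenicity <- function(model, features) {
  stopifnot(inherits(model, "ss_effect_model"),
            model$purpose == "pathogenicity")
  as.vector(stats::predict(model$glm, newdata = features, type = "response"))
}

#' K-fold cross-validated pathogenicity evaluation
#'
#' @inheritParams fit_pathogenicity
#' @param k Number of folds (default 10).
#' @param seed Integer seed for the fold assignment.
#' @return List with out-of-fold `prob` predictions, `label`, and `auroc`.
#' @export
cv_pathogenicity <- function(rows, feature_set = c("delta", "delta_ref"),
                             k = 10L, seed = 1L) {
  feature_set <- match.arg(feature_set)
  n <- nrow(rows)
  stopifnot(n >= k, k >= 2L)
  set.seed(seed)
  fold <- sample(rep_len(seq_len(k), n))
  prob <- numeric(n)
  for (f in seq_len(k)) {
    m <- fit_pathogenicity(rows[fold != f, , drop = FALSE], feature_set)
    prob[fold == f] <- predict_pathogenicity(m, rows[fold == f, , drop = FALSE])
  }
  list(prob = prob, label = rows$label,
       auroc = metric("auROC", rows$label, prob))
}

#' Rank variants as splice-disrupting
#'
#' Ranks variants by the magnitude of their predicted delta-PSI (direction
#' is deliberately ignored: a splice-disrupting variant may increase or
#' decrease inclusion) for precision-recall evaluation; an optional
#' threshold adds hard calls.
#'
#' @param delta_psi Numeric vector of predicted delta-PSI values.
#' @param threshold Optional |delta-PSI| cutoff for a hard call.
#' @return Data frame with `score` (|delta-PSI|), `rank` (1 = most
#'   disruptive, average rank on ties), and `call` if a threshold was given.
#' @export
classify_sdv <- function(delta_psi, threshold = NULL) {
  stopifnot(all(is.finite(delta_psi)))
  score <- abs(delta_psi)
  out <- data.frame(score = score, rank = rank(-score, ties.method = "average"))
  if (!is.null(threshold)) out$call <- score >= threshold
  out
}

#' Per-variant aggregation over multiple exon pairs
#'
#' A variant paired with several exons gets one prediction per pair; for
#' variant-level benchmarking the effect with the largest magnitude is
#' reported (all per-pair rows are kept by the scoring pipeline).
#'
#' @param variant_id Character vector, one entry per pair.
#' @param effect Numeric vector of per-pair effects.
#' @return Data frame with one row per variant: `variant_id`, `effect` (the
#'   signed effect of largest magnitude).
#' @export
aggregate_by_variant <- function(variant_id, effect) {
  stopifnot(length(variant_id) == length(effect))
  sp <- split(effect, variant_id)
  data.frame(variant_id = names(sp),
             effect = vapply(sp, function(e) e[which.max(abs(e))], numeric(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}
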