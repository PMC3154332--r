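#' Backward-deletion GLMs of PCR product polymorphism
#'
#' Fits a generalized linear model of PCR polymorphism and simplifies it
#' by standard deletion testing: at each step the term whose removal
#' costs the least deviance is dropped, unless that removal
#' significantly reduces the deviance explained (likelihood-ratio
#' chi-square at level `alpha`, degrees of freedom equal to the
#' parameter-count difference). The binary analysis models
#' polymorphic/monomorphic with a binomial error structure; restricted
#' to polymorphic loci, the allele-count analysis uses a Poisson error
#' structure (log link).
#'
#' Typical predictors are the minimum number of repeat units observed in
#' silico (a length proxy: the shortest allele among reads), the number
#' of reads differing from the consensus, the number of in silico
#' alleles (continuous), selection category and motif size (factors),
#' and — binomial model only — the binary in silico variability call.
#'
#' @param records Complete-case data.frame of locus records.
#' @param response Name of the response column (e.g. `polymorphic_pcr`
#'   coded 0/1, or `n_alleles_observed`).
#' @param predictors Character vector of predictor column names.
#' @param family `"binomial"` or `"poisson"`.
#' @param alpha Deletion-test significance level (default 0.05).
#' @return List with elements `model` (the reduced `glm` fit), `terms`
#'   (data.frame of retained terms: `term`, `estimate` — the
#'   coefficient, or `NA` for multi-level factors —, `chisq`, `df`,
#'   `p` from the deletion test of each retained term against the
#'   reduced model), `dropped` (terms removed, in order),
#'   `nullDeviance`, `residualDeviance`, `explainedDeviancePct`, and
#'   `separationFlag` (`TRUE` when the fit showed numerically 0/1
#'   fitted probabilities, i.e. likely complete separation).
#' @examples
#' d <- data.frame(y = rbinom(40, 1, 0.5), x = rnorm(40))
#' fitPolymorphismGlms(d, "y", "x", family = "binomial")$terms
#' @export
fitPolymorphismGlms <- function(records, response, predictors,
                                family = c("binomial", "poisson"),
                                alpha = 0.05) {
  family <- match.arg(family)
  stopifnot(all(c(response, predictors) %in% names(records)))
  records <- records[stats::complete.cases(
    records[, c(response, predictors), drop = FALSE]), , drop = FALSE]
  nParFull <- 1L + sum(vapply(predictors, function(p) {
    x <- records[[p]]
    if (is.factor(x) || is.character(x))
      max(1L, length(unique(x)) - 1L) else 1L
  }, integer(1L)))
  if (nrow(records) < nParFull)
    stop(sprintf("only %d records for %d model parameters",
                 nrow(records), nParFull))

  sepFlag <- FALSE
  muffleSeparation <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w))) {
        sepFlag <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  }
  fitGlm <- function(terms) {
    rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
    fml <- stats::as.formula(paste(response, "~", rhs))
    muffleSeparation(stats::glm(fml, family = family, data = records))
  }

  terms <- predictors
  fit <- fitGlm(terms)
  dropped <- character(0)
  while (length(terms)) {
    d1 <- muffleSeparation(stats::drop1(fit, test = "Chisq"))
    cand <- rownames(d1)[-1L]
    pvals <- d1$`Pr(>Chi)`[-1L]
    worst <- which.max(pvals)
    if (length(worst) == 0L || pvals[worst] <= alpha) break
    dropped <- c(dropped, cand[worst])
    terms <- setdiff(terms, cand[worst])
    fit <- fitGlm(terms)
  }

  termTable <- data.frame(term = character(0), estimate = numeric(0),
                          chisq = numeric(0), df = integer(0),
                          p = numeric(0), stringsAsFactors = FALSE)
  if (length(terms)) {
    d1 <- muffleSeparation(stats::drop1(fit, test = "Chisq"))
    cand <- rownames(d1)[-1L]
    est <- vapply(cand, function(tm) {
      cf <- stats::coef(fit)
      hit <- which(names(cf) == tm)
      if (length(hit) == 1L) unname(cf[hit]) else NA_real_
    }, numeric(1L))
    termTable <- data.frame(term = cand, estimate = est,
                            chisq = d1$LRT[-1L], df = d1$Df[-1L],
                            p = d1$`Pr(>Chi)`[-1L],
                            stringsAsFactors = FALSE)
  }
  if (sepFlag)
    warning("possible complete separation: fitted probabilities ",
            "numerically 0 or 1; estimates are unreliable")
  nullDev <- fit$null.deviance
  resDev <- fit$deviance
  list(model = fit, terms = termTable, dropped = dropped,
       nullDeviance = nullDev, residualDeviance = resDev,
       explainedDeviancePct =
         if (nullDev > 0) 100 * (nullDev - resDev) / nullDev else 0,
       separationFlag = sepFlag)
}
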