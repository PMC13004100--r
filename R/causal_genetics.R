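# Summary-statistic causal genetics: Wald-ratio MR, Wakefield-ABF
# colocalization, credible sets from PIPs, LD r^2, criteria-based variant
# prioritization.

#' Construct/validate a GWAS summary-statistic record
#'
#' @param variant_id,chromosome,position,effect_allele,other_allele variant
#'   identity.
#' @param eaf effect-allele frequency in (0, 1).
#' @param beta,se effect estimate and its standard error (> 0).
#' @param p association p-value in (0, 1].
#' @param n sample count.
#' @return one-row data frame of class `"summary_stat"`.
#' @export
summary_stat <- function(variant_id, chromosome, position, effect_allele,
                         other_allele, eaf, beta, se, p = NA_real_, n = NA_real_) {
  if (se <= 0) stop("se must be > 0")
  if (!is.na(eaf) && (eaf <= 0 || eaf >= 1)) stop("eaf must lie in (0, 1)")
  if (effect_allele == other_allele) stop("alleles must differ")
  out <- data.frame(variant_id = variant_id, chromosome = as.character(chromosome),
                    position = as.integer(position),
                    effect_allele = effect_allele, other_allele = other_allele,
                    eaf = eaf, beta = beta, se = se, p = p, n = n,
                    stringsAsFactors = FALSE)
  class(out) <- c("summary_stat", class(out))
  out
}

is_strand_ambiguous <- function(a1, a2) {
  pair <- paste(toupper(a1), toupper(a2))
  pair %in% c("A T", "T A", "C G", "G C")
}

# Align an outcome record to the exposure's effect allele.  Swapped alleles
# flip the outcome beta (and eaf); anything else is an unresolvable
# mismatch.  Strand-ambiguous variants are kept with a warning, frequency-
# checked when EAF is available on both sides.
harmonize_pair <- function(exposure, outcome) {
  if (exposure$variant_id != outcome$variant_id)
    stop("records refer to different variants")
  ea <- toupper(exposure$effect_allele); oa <- toupper(exposure$other_allele)
  eb <- toupper(outcome$effect_allele); ob <- toupper(outcome$other_allele)
  if (is_strand_ambiguous(ea, oa)) {
    msg <- paste0("variant ", exposure$variant_id,
                  " is strand-ambiguous (", ea, "/", oa, "); kept")
    if (!is.na(exposure$eaf) && !is.na(outcome$eaf) &&
        abs(exposure$eaf - outcome$eaf) > 0.2 &&
        abs(exposure$eaf - (1 - outcome$eaf)) < abs(exposure$eaf - outcome$eaf))
      msg <- paste0(msg, "; EAFs suggest opposite strands, check inputs")
    warning(msg, call. = FALSE)
  }
  if (eb == ea && ob == oa) return(outcome)
  if (eb == oa && ob == ea) {
    outcome$beta <- -outcome$beta
    outcome$effect_allele <- exposure$effect_allele
    outcome$other_allele <- exposure$other_allele
    if (!is.na(outcome$eaf)) outcome$eaf <- 1 - outcome$eaf
    return(outcome)
  }
  stop("allele mismatch for ", exposure$variant_id, ": ", ea, "/", oa,
       " vs ", eb, "/", ob, " cannot be resolved by flipping")
}

#' Wald-ratio Mendelian randomization for a single instrument
#'
#' Causal effect of the exposure on the outcome as `beta_out / beta_exp`,
#' with the first-order standard error `se_out / |beta_exp|` under the NOME
#' (No Measurement Error) assumption — the exposure effect is treated as
#' known.  The instrument strength is the exposure F-statistic
#' `(beta_exp / se_exp)^2`.  Outcome alleles are auto-flipped when swapped
#' relative to the exposure.
#'
#' @param exposure,outcome [summary_stat()] records for the same variant.
#' @return list of class `"wald_result"`: `ratio`, `se_ratio`, `p`
#'   (two-sided normal), `f_statistic`.
#' @export
wald_ratio_mr <- function(exposure, outcome) {
  outcome <- harmonize_pair(exposure, outcome)
  if (exposure$beta == 0)
    stop("undefined instrument: exposure beta is 0")
  ratio <- outcome$beta / exposure$beta
  se_ratio <- outcome$se / abs(exposure$beta)
  structure(list(ratio = ratio, se_ratio = se_ratio,
                 p = 2 * pnorm(-abs(ratio / se_ratio)),
                 f_statistic = (exposure$beta / exposure$se)^2),
            class = "wald_result")
}

#' Wakefield log approximate Bayes factor
#'
#' For an estimate `beta` with standard error `se` and a `N(0, W^2)` prior
#' on the true effect: with `z = beta/se` and `r = W^2 / (W^2 + se^2)`,
#' `labf = 0.5 * (log(1 - r) + r * z^2)`.  Vectorised over all arguments.
#'
#' @param beta,se estimate and standard error (`se > 0`).
#' @param prior_sd prior standard deviation `W > 0`.
#' @return log Bayes factor(s) in favour of a nonzero effect.
#' @export
wakefield_labf <- function(beta, se, prior_sd) {
  stopifnot(all(se > 0), all(prior_sd > 0))
  z <- beta / se
  r <- prior_sd^2 / (prior_sd^2 + se^2)
  0.5 * (log1p(-r) + r * z^2)
}

#' Approximate-Bayes-factor colocalization of two traits
#'
#' Enumerates the five configurations (no association, trait-1 only,
#' trait-2 only, two distinct causal variants, one shared causal variant)
#' over a shared variant set, scoring each variant by its Wakefield log-ABF
#' per trait and combining with the prior probabilities `p1`, `p2`, `p12`
#' via log-sum-exp.  The per-variant posterior for the shared-signal
#' configuration is the normalised `exp(labf1 + labf2)`.
#'
#' @param trait1,trait2 data frames of summary statistics (columns
#'   `variant_id`, `beta`, `se`) over the same variants, harmonised to the
#'   same effect alleles and order.
#' @param p1,p2,p12 prior probabilities that a variant is causal for trait
#'   1 only, trait 2 only, or both.
#' @param prior_sd1,prior_sd2 effect prior standard deviations; 0.15 is the
#'   usual choice for a quantitative trait in standard-deviation units, 0.2
#'   for a binary trait on the log-odds scale.
#' @return list of class `"coloc_result"`: `pp` (named PP0..PP4, sums to
#'   1), `per_variant_pp4` (named, sums to 1), `priors`, `n_variants`.
#' @export
coloc_abf <- function(trait1, trait2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                      prior_sd1 = 0.15, prior_sd2 = 0.15) {
  if (anyDuplicated(trait1$variant_id) || anyDuplicated(trait2$variant_id))
    stop("duplicate variant ids")
  shared <- intersect(trait1$variant_id, trait2$variant_id)
  if (length(shared) < 2L) stop("need >= 2 shared variants")
  t1 <- trait1[match(shared, trait1$variant_id), ]
  t2 <- trait2[match(shared, trait2$variant_id), ]
  l1 <- wakefield_labf(t1$beta, t1$se, prior_sd1)
  l2 <- wakefield_labf(t2$beta, t2$se, prior_sd2)
  s1 <- logsumexp(l1)
  s2 <- logsumexp(l2)
  s12 <- logsumexp(l1 + l2)
  # sum over ordered pairs i != j of exp(l1_i + l2_j), in log space
  cross <- s1 + s2
  lh <- c(H0 = 0,
          H1 = log(p1) + s1,
          H2 = log(p2) + s2,
          H3 = log(p1) + log(p2) + cross + log1p(-exp(s12 - cross)),
          H4 = log(p12) + s12)
  pp <- exp(lh - logsumexp(lh))
  names(pp) <- paste0("PP", 0:4)
  pv <- exp((l1 + l2) - s12)
  names(pv) <- shared
  structure(list(pp = pp, per_variant_pp4 = pv,
                 priors = c(p1 = p1, p2 = p2, p12 = p12),
                 n_variants = length(shared)),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat("ABF colocalization over", x$n_variants, "variants\n")
  print(round(x$pp, 4))
  top <- which.max(x$per_variant_pp4)
  cat(sprintf("lead shared-signal variant: %s (per-variant PP4 = %.3f)\n",
              names(top), x$per_variant_pp4[top]))
  invisible(x)
}

#' Credible set from posterior inclusion probabilities
#'
#' Sorts variants by decreasing PIP (ties broken by variant id) and
#' accumulates until the cumulative PIP reaches the coverage level; the
#' result is minimal by construction (dropping the last member falls below
#' coverage).
#'
#' @param pips named numeric vector of PIPs in `[0, 1]`.
#' @param coverage target coverage probability (default 0.95).
#' @return list of class `"credible_set"`: `members` (data frame
#'   `variant_id`, `pip`, `cumulative_pip`, in decreasing-PIP order),
#'   `coverage_level`, `cumulative_pip`.
#' @export
credible_set_from_pips <- function(pips, coverage = 0.95) {
  if (is.null(names(pips))) names(pips) <- paste0("v", seq_along(pips))
  if (any(pips < 0 | pips > 1)) stop("PIPs must lie in [0, 1]")
  total <- sum(pips)
  if (total < coverage)
    stop(sprintf("total PIP %.4f < coverage %.2f: achievable coverage is %.4f",
                 total, coverage, total))
  ord <- order(-pips, names(pips))
  cum <- cumsum(pips[ord])
  k <- which(cum >= coverage)[1]
  members <- data.frame(variant_id = names(pips)[ord][seq_len(k)],
                        pip = as.numeric(pips[ord][seq_len(k)]),
                        cumulative_pip = as.numeric(cum[seq_len(k)]),
                        stringsAsFactors = FALSE)
  structure(list(members = members, coverage_level = coverage,
                 cumulative_pip = cum[[k]]),
            class = "credible_set")
}

#' @export
print.credible_set <- function(x, ...) {
  cat(sprintf("%d%% credible set: %d variants, cumulative PIP %.3f\n",
              round(100 * x$coverage_level), nrow(x$members),
              x$cumulative_pip))
  invisible(x)
}

#' Pairwise LD as squared dosage correlation
#'
#' @param genotypes samples x variants dosage matrix (column names are
#'   variant ids).
#' @return symmetric matrix of squared Pearson correlations (diagonal 1).
#' @export
ld_r2_matrix <- function(genotypes) {
  genotypes <- as.matrix(genotypes)
  if (nrow(genotypes) < 2L) stop("need >= 2 samples")
  v <- apply(genotypes, 2, var)
  if (any(v == 0)) {
    bad <- colnames(genotypes)[v == 0]
    if (is.null(bad)) bad <- which(v == 0)
    stop("monomorphic variant(s): ", paste(bad, collapse = ", "))
  }
  r2 <- cor(genotypes)^2
  diag(r2) <- 1
  r2
}

#' Criteria-based variant prioritization
#'
#' Non-coding variants are prioritized when at least two of the four
#' functional-evidence criteria hold: narrow-peak-supported regulatory
#' overlap, a predicted enhancer-gene regulatory link, association with
#' *increased* target expression/protein level, and QTL colocalization.
#' Overlap supported only by gapped peaks is recorded but does not count.
#' Coding non-synonymous variants are flagged as prioritized and annotated
#' with the fraction of variant-effect predictors voting deleterious.
#'
#' @param records data frame with columns `variant_id`,
#'   `is_coding_nonsynonymous`, the logical criteria `regulatory_overlap`,
#'   `re2g_link`, `increases_expression`, `qtl_colocalizes`, and for coding
#'   variants `deleterious_votes`, `total_predictors`.
#' @return the records with added `n_criteria_met`, `deleterious_fraction`
#'   and `prioritized` columns.
#' @export
prioritize_variants <- function(records) {
  need <- c("variant_id", "is_coding_nonsynonymous", "regulatory_overlap",
            "re2g_link", "increases_expression", "qtl_colocalizes")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  crit <- as.matrix(records[, c("regulatory_overlap", "re2g_link",
                                "increases_expression", "qtl_colocalizes")])
  records$n_criteria_met <- rowSums(crit, na.rm = TRUE)
  records$deleterious_fraction <- NA_real_
  coding <- records$is_coding_nonsynonymous
  if (any(coding)) {
    if (!all(c("deleterious_votes", "total_predictors") %in% names(records)))
      stop("coding variants need deleterious_votes and total_predictors")
    votes <- records$deleterious_votes[coding]
    tot <- records$total_predictors[coding]
    if (any(votes > tot)) stop("deleterious_votes exceeds total_predictors")
    records$deleterious_fraction[coding] <- votes / tot
  }
  records$prioritized <- ifelse(coding, TRUE, records$n_criteria_met >= 2)
  records
}
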