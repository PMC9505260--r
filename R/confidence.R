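#' Extract per-residue confidence (pLDDT) from the B-factor column
#'
#' AlphaFold/RoseTTAFold-style models store the per-residue pLDDT score in
#' the B-factor field. The per-residue score is taken from the CA atom
#' (falling back to the mean over the residue's atoms when CA is absent).
#' Some predictors emit scores on a 0-1 scale; `scale = "auto"` detects
#' this (maximum B-factor <= 1) and rescales to 0-100.
#'
#' @param s `pg_structure`.
#' @param scale "auto", "0-100" (use B-factors as-is) or "0-1" (multiply
#'   by 100).
#' @param chain optional chain filter.
#' @return data.frame with columns chain, resno, insert, resid, plddt
#'   (0-100 scale).
#' @export
extract_plddt <- function(s, scale = c("auto", "0-100", "0-1"),
                          chain = NULL) {
  scale <- match.arg(scale)
  a <- s$atoms
  a <- a[a$type == "ATOM", , drop = FALSE]
  if (!is.null(chain)) a <- a[a$chain %in% chain, , drop = FALSE]
  if (nrow(a) == 0L) stop("no polymer atoms to extract confidence from")
  key <- res_key(a$chain, a$resno, a$insert)
  res <- a[!duplicated(key), c("chain", "resno", "insert", "resid")]
  ukey <- key[!duplicated(key)]
  is_ca <- a$elety == "CA"
  score <- vapply(ukey, function(k) {
    i <- which(key == k)
    ca <- i[is_ca[i]]
    if (length(ca)) a$b[ca[1]] else mean(a$b[i])
  }, numeric(1))
  bad <- !is.finite(score)
  if (any(bad)) {
    warning(sum(bad), " residue(s) without usable B-factors omitted")
    res <- res[!bad, , drop = FALSE]; score <- score[!bad]
  }
  if (scale == "0-1" || (scale == "auto" && max(score) <= 1.0))
    score <- score * 100
  res$plddt <- unname(score)
  rownames(res) <- NULL
  res
}

#' Per-domain and whole-model mean pLDDT
#'
#' Arithmetic mean of per-residue scores within each assigned domain, plus
#' a "Whole" row over all scored residues. The Whole mean is by
#' construction the residue-count-weighted mean of the domain means
#' (including any "other" residues).
#'
#' @param scores data.frame from [extract_plddt] (columns resno, plddt at
#'   minimum).
#' @param domains either a [domain_scheme] or a per-residue assignment
#'   data.frame from [assign_domains] (columns resno, domain).
#' @return data.frame with columns domain, mean_plddt, n_residues; the
#'   last row is "Whole".
#' @export
domain_plddt <- function(scores, domains) {
  if (nrow(scores) == 0L) stop("no scores supplied")
  if (inherits(domains, "pg_domain_scheme")) {
    lab <- domain_of(scores$resno, domains)
    order_names <- c(rownames(domains$ranges), "other")
  } else {
    m <- match(scores$resno, domains$resno)
    lab <- domains$domain[m]
    if (anyNA(lab)) {
      warning(sum(is.na(lab)), " scored residue(s) missing from the ",
              "domain assignment treated as 'other'")
      lab[is.na(lab)] <- "other"
    }
    order_names <- c(unique(domains$domain), "other")
  }
  means <- tapply(scores$plddt, lab, mean)
  ns <- tapply(scores$plddt, lab, length)
  nm <- intersect(unique(order_names), names(means))
  out <- data.frame(domain = c(nm, "Whole"),
                    mean_plddt = c(unname(means[nm]), mean(scores$plddt)),
                    n_residues = c(as.integer(ns[nm]), nrow(scores)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Mean and standard deviation of whole-model scores across a model set
#'
#' Summarizes the "Whole" pLDDT of several models from one predictor, as
#' in reporting e.g. 79.9 +/- 0.9 across five models. Both the population
#' (divide by n) and sample (divide by n-1) standard deviations are
#' meaningful for a complete set of five models; published summaries mix
#' the two conventions, so the kind is explicit and both are available.
#'
#' @param whole_scores numeric vector of per-model whole-structure means.
#' @param std_kind "population" (default) or "sample".
#' @return list with `mean`, `sd` (NA when fewer than 2 models), `n`,
#'   `std_kind`.
#' @export
summarize_models <- function(whole_scores,
                             std_kind = c("population", "sample")) {
  std_kind <- match.arg(std_kind)
  n <- length(whole_scores)
  m <- mean(whole_scores)
  s <- if (n < 2L) NA_real_
  else if (std_kind == "sample") sd(whole_scores)
  else sqrt(mean((whole_scores - m)^2))
  list(mean = m, sd = s, n = n, std_kind = std_kind)
}

#' Confidence band of a pLDDT score
#'
#' Bands follow the standard pLDDT interpretation: above 90 high accuracy,
#' 70-90 moderate to good, 50-70 low confidence, below 50 disordered or
#' unstructured. Boundary scores belong to the higher band (90 is "high",
#' 70 "moderate", 50 "low").
#'
#' @param score numeric vector on the 0-100 scale.
#' @return character vector: "high", "moderate", "low" or "disordered".
#' @export
classify_confidence <- function(score) {
  if (any(!is.finite(score) | score < 0 | score > 100))
    stop("scores must be finite and within [0, 100]")
  cut(score, breaks = c(-Inf, 50, 70, 90, Inf), right = FALSE,
      labels = c("disordered", "low", "moderate", "high")) |>
    as.character()
}
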