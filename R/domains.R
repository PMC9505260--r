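#' Domain scheme: named residue ranges plus key-residue and motif constants
#'
#' A domain scheme partitions a chain into named, non-overlapping inclusive
#' author-numbered residue intervals, and optionally carries a key-residue
#' table (residue number + expected 3-letter code) and named sequence
#' motifs.
#'
#' @param ranges named list of `c(start, end)` inclusive intervals.
#' @param key_residues optional data.frame with columns `resno`, `resid`.
#' @param motifs optional named character vector of sequence motifs.
#' @return object of class `pg_domain_scheme`.
#' @export
domain_scheme <- function(ranges, key_residues = NULL, motifs = NULL) {
  if (length(ranges) == 0L || is.null(names(ranges)) ||
      any(names(ranges) == ""))
    stop("ranges must be a non-empty named list")
  rng <- t(vapply(ranges, function(r) {
    if (length(r) != 2L || r[1] > r[2]) stop("each range must be c(start, end) with start <= end")
    as.integer(r)
  }, integer(2)))
  colnames(rng) <- c("start", "end")
  ord <- order(rng[, "start"])
  r2 <- rng[ord, , drop = FALSE]
  if (nrow(r2) > 1L && any(r2[-1, "start"] <= r2[-nrow(r2), "end"]))
    stop("domain ranges overlap")
  structure(list(ranges = rng, key_residues = key_residues, motifs = motifs),
            class = "pg_domain_scheme")
}

#' @export
print.pg_domain_scheme <- function(x, ...) {
  cat("<pg_domain_scheme>\n")
  for (i in seq_len(nrow(x$ranges)))
    cat(sprintf("  %-6s %d-%d\n", rownames(x$ranges)[i],
                x$ranges[i, 1], x$ranges[i, 2]))
  if (!is.null(x$key_residues))
    cat("  key residues:",
        paste(residue_label(x$key_residues$resid, x$key_residues$resno),
              collapse = " "), "\n")
  invisible(x)
}

#' The NLRP3 subdomain scheme
#'
#' Human NLRP3 subdomain boundaries in author numbering: PYD 3-95, FISNA
#' 96-218, then the NACHT constituents NBD 219-372, HD1 373-434, WHD
#' 435-541, HD2 542-651, and LRR 652-1036. Key residues line the MCC950
#' binding cleft at the NBD/HD1/WHD/HD2/LRR interface (A228 sits in the
#' Walker A motif of NBD; F575/R578/E629 in HD2; I411/Y443 in HD1; E636 and
#' D662 are alternative salt-bridge partners of R578). Residue 629 is
#' carried under both the GLU and GLY labels because published descriptions
#' disagree; validation against the actual sequence is left to the caller
#' and never silently corrected.
#'
#' @return a [domain_scheme].
#' @export
nlrp3_scheme <- function() {
  domain_scheme(
    ranges = list(PYD = c(3, 95), FISNA = c(96, 218), NBD = c(219, 372),
                  HD1 = c(373, 434), WHD = c(435, 541), HD2 = c(542, 651),
                  LRR = c(652, 1036)),
    key_residues = data.frame(
      resno = c(228L, 411L, 443L, 575L, 578L, 629L, 629L, 636L, 662L),
      resid = c("ALA", "ILE", "TYR", "PHE", "ARG", "GLU", "GLY", "GLU",
                "ASP"),
      stringsAsFactors = FALSE),
    motifs = c(walker_a = "GAAGIGKTIL",
               walker_b = "RILFMDGFDELQGAFDEHI"))
}

# domain name for each author residue number ("other" outside all ranges)
domain_of <- function(resno, scheme) {
  out <- rep("other", length(resno))
  rng <- scheme$ranges
  for (i in seq_len(nrow(rng)))
    out[resno >= rng[i, "start"] & resno <= rng[i, "end"]] <-
      rownames(rng)[i]
  out
}

#' Assign residues of a chain to named domains
#'
#' Every residue whose author number lies inside a scheme range gets that
#' range's name; residues outside all ranges are labeled "other", so the
#' result is a partition of the chain.
#'
#' @param s `pg_structure`.
#' @param scheme a [domain_scheme].
#' @param chain chain id.
#' @return data.frame with columns chain, resno, insert, resid, domain.
#' @export
assign_domains <- function(s, scheme, chain) {
  res <- residue_table(s, chain = chain)
  if (nrow(res) == 0L) stop("chain not found: ", chain)
  res$domain <- domain_of(res$resno, scheme)
  res
}

#' Fraction of a domain's residues missing from a structure
#'
#' A residue counts as present when it appears with at least one
#' non-hydrogen atom. The fraction is relative to the full range length
#' (end - start + 1), mirroring how missing density is reported for
#' experimental structures.
#'
#' @param s `pg_structure`.
#' @param scheme a [domain_scheme].
#' @param domain domain name in the scheme.
#' @param chain chain id.
#' @return list with `fraction` (0-1), `absent` (integer residue numbers),
#'   `n_range`, `n_present`.
#' @export
missing_fraction <- function(s, scheme, domain, chain) {
  rng <- scheme$ranges
  if (!domain %in% rownames(rng)) stop("unknown domain: ", domain)
  lo <- rng[domain, "start"]; hi <- rng[domain, "end"]
  a <- s$atoms
  a <- a[a$chain == chain & a$type == "ATOM" & !is_hydrogen(a), ,
         drop = FALSE]
  present <- unique(a$resno[a$resno >= lo & a$resno <= hi])
  all_res <- lo:hi
  absent <- setdiff(all_res, present)
  list(fraction = length(absent) / length(all_res),
       absent = sort(absent),
       n_range = length(all_res),
       n_present = length(all_res) - length(absent))
}
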