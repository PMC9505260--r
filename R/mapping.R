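# the standard proteinogenic residues eligible for model/reference mapping
STD_AA <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
            "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
            "TYR", "VAL")

#' Residue correspondence between a model and a reference structure
#'
#' Establishes one-to-one residue pairs between a predicted model chain and
#' an experimental reference chain that may have missing residues. Two
#' modes:
#'
#' * `by-number` (default): pair residues sharing author number + insertion
#'   code and an identical 3-letter code. Number matches with differing
#'   residue names are excluded with a warning. This is the right mode when
#'   model and experiment share deposited numbering.
#' * `by-alignment`: global (Needleman-Wunsch) alignment of the one-letter
#'   sequences (match +1, mismatch -1, gap open 5, gap extension 0.5 as
#'   positive costs); pairs are taken from aligned identical columns. Use
#'   for renumbered inputs. Requires the Biostrings package.
#'
#' Only standard amino-acid (ATOM) residues participate; HETATM ligands are
#' handled by the interaction/trajectory functions explicitly.
#'
#' @param model,reference `pg_structure` objects.
#' @param model_chain,ref_chain chain ids.
#' @param mode "by-number" or "by-alignment".
#' @return object of class `pg_mapping`: a data.frame with columns
#'   model_resno, model_insert, model_resid, ref_resno, ref_insert,
#'   ref_resid, plus attributes `mode`, `model_chain`, `ref_chain`.
#' @export
map_residues <- function(model, reference, model_chain, ref_chain,
                         mode = c("by-number", "by-alignment")) {
  mode <- match.arg(mode)
  mres <- residue_table(model, chain = model_chain)
  rres <- residue_table(reference, chain = ref_chain)
  if (nrow(mres) == 0L) stop("model chain not found: ", model_chain)
  if (nrow(rres) == 0L) stop("reference chain not found: ", ref_chain)
  mres <- mres[mres$resid %in% STD_AA, , drop = FALSE]
  rres <- rres[rres$resid %in% STD_AA, , drop = FALSE]

  if (mode == "by-number") {
    mk <- paste(mres$resno, mres$insert, sep = "\r")
    rk <- paste(rres$resno, rres$insert, sep = "\r")
    common <- intersect(mk, rk)
    mi <- match(common, mk); ri <- match(common, rk)
    same <- mres$resid[mi] == rres$resid[ri]
    if (any(!same))
      warning(sum(!same), " residue number match(es) with differing ",
              "residue names excluded (e.g. ",
              residue_label(mres$resid[mi[!same][1]],
                            mres$resno[mi[!same][1]]), " vs ",
              residue_label(rres$resid[ri[!same][1]],
                            rres$resno[ri[!same][1]]), ")")
    mi <- mi[same]; ri <- ri[same]
  } else {
    if (!requireNamespace("Biostrings", quietly = TRUE))
      stop("mode 'by-alignment' requires the Biostrings package")
    mseq <- suppressWarnings(bio3d::aa321(mres$resid))
    rseq <- suppressWarnings(bio3d::aa321(rres$resid))
    al <- align_pairs(mseq, rseq)
    keep <- mseq[al[, 1]] == rseq[al[, 2]]
    mi <- al[keep, 1]; ri <- al[keep, 2]
  }
  if (length(mi) == 0L) stop("no mappable residues between the chains")
  out <- data.frame(model_resno = mres$resno[mi],
                    model_insert = mres$insert[mi],
                    model_resid = mres$resid[mi],
                    ref_resno = rres$resno[ri],
                    ref_insert = rres$insert[ri],
                    ref_resid = rres$resid[ri],
                    stringsAsFactors = FALSE)
  attr(out, "mode") <- mode
  attr(out, "model_chain") <- model_chain
  attr(out, "ref_chain") <- ref_chain
  class(out) <- c("pg_mapping", "data.frame")
  out
}

# aligned position pairs (i, j) from a global pairwise alignment
align_pairs <- function(seq_a, seq_b) {
  letters_ab <- unique(c(seq_a, seq_b, "X"))
  sm <- matrix(-1, length(letters_ab), length(letters_ab),
               dimnames = list(letters_ab, letters_ab))
  diag(sm) <- 1
  al <- Biostrings::pairwiseAlignment(
    paste(seq_a, collapse = ""), paste(seq_b, collapse = ""),
    type = "global", substitutionMatrix = sm,
    gapOpening = 5, gapExtension = 0.5)
  pa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  ps <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  ia <- cumsum(pa != "-"); ib <- cumsum(ps != "-")
  both <- pa != "-" & ps != "-"
  cbind(ia[both], ib[both])
}

#' Atom pairing from a residue mapping
#'
#' Within each mapped residue pair, atoms are matched by atom name; atoms
#' present on only one side are skipped (no imputation for partially
#' modeled side chains). `selection = "heavy"` pairs all non-hydrogen
#' atoms, `"calpha"` pairs CA atoms only.
#'
#' @param model,reference the structures the mapping was built from.
#' @param mapping a `pg_mapping`.
#' @param selection "heavy" or "calpha".
#' @return object of class `pg_atom_pairing`: list with `model_idx` and
#'   `ref_idx` (row indices into each structure's atom table, same
#'   length), `resno` (model residue number per pair), `elety`,
#'   `selection`.
#' @export
pair_atoms <- function(model, reference, mapping,
                       selection = c("heavy", "calpha")) {
  selection <- match.arg(selection)
  if (nrow(mapping) == 0L) stop("empty residue mapping")
  ma <- model$atoms; ra <- reference$atoms
  mc <- attr(mapping, "model_chain"); rc <- attr(mapping, "ref_chain")
  m_ok <- ma$type == "ATOM" & ma$chain == mc & !is_hydrogen(ma)
  r_ok <- ra$type == "ATOM" & ra$chain == rc & !is_hydrogen(ra)
  if (selection == "calpha") {
    m_ok <- m_ok & ma$elety == "CA"
    r_ok <- r_ok & ra$elety == "CA"
  }
  mkey <- res_key(ma$chain, ma$resno, ma$insert)
  rkey <- res_key(ra$chain, ra$resno, ra$insert)
  mi_all <- ri_all <- vector("list", nrow(mapping))
  for (i in seq_len(nrow(mapping))) {
    mi <- which(m_ok & mkey == res_key(mc, mapping$model_resno[i],
                                       mapping$model_insert[i]))
    ri <- which(r_ok & rkey == res_key(rc, mapping$ref_resno[i],
                                       mapping$ref_insert[i]))
    shared <- intersect(ma$elety[mi], ra$elety[ri])
    if (length(shared) == 0L) next
    mi_all[[i]] <- mi[match(shared, ma$elety[mi])]
    ri_all[[i]] <- ri[match(shared, ra$elety[ri])]
  }
  midx <- unlist(mi_all); ridx <- unlist(ri_all)
  if (length(midx) == 0L) stop("zero paired atoms for selection ", selection)
  structure(list(model_idx = midx, ref_idx = ridx,
                 resno = ma$resno[midx], elety = ma$elety[midx],
                 selection = selection),
            class = "pg_atom_pairing")
}

#' @export
print.pg_atom_pairing <- function(x, ...) {
  cat(sprintf("<pg_atom_pairing> %d %s-atom pairs over %d residues\n",
              length(x$model_idx), x$selection, length(unique(x$resno))))
  invisible(x)
}
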