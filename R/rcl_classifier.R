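# Schechter-Berger numbering of RCL residues and P1-based prediction of
# target protease classes.
#
# In Schechter-Berger substrate nomenclature, P1 and P1' flank the scissile
# bond: Pk counts k residues upstream of the cleaved bond, Pk' counts
# downstream. The classifier is a screening-level rule table keyed on P1
# (with P1' refining the hydrophobic cases):
#   1. P1 in {V, I} with small P1' (A/S/G/T)      -> dual
#      (chymotrypsin-like and elastase-like preference)
#   2. P1 in {R, K}                                -> coagulation_complement
#      (trypsin-like targets: thrombin, fXa/fXIa, kallikrein, C1r/C1s/MASP)
#   3. P1 in {F, Y, W, L, I, V, M}                 -> inflammation_control
#      (chymotrypsin-like: cathepsin G, mast-cell chymase)
#   4. P1 in {A, S, G}                             -> tissue_protection
#      (elastase-like: neutrophil elastase, proteinase 3)
#   5. otherwise (e.g. N, E)                       -> unknown
# The dual rule strictly precedes the hydrophobic rule.

.P1_CLASSES <- c("coagulation_complement", "inflammation_control",
                 "tissue_protection", "dual", "unknown")

#' Number RCL residues in Schechter-Berger convention
#'
#' @param protein Protein string.
#' @param rcl_start,rcl_end 1-based inclusive RCL match coordinates in the
#'   protein (e.g. from [scan_protein()]).
#' @param scissile_offset 1-based position of P1 within the RCL match (the
#'   scissile bond lies between this residue and the next). Typically carried
#'   as metadata on the seed RCL and propagated to hits by alignment position.
#' @return List of class `rcl_annotation`: `positions` (named residue vector
#'   P15..P1, P1'..P4'; positions outside the protein are NA/absent), `p1`,
#'   `p1_prime`, `predicted_class`.
#' @export
number_rcl <- function(protein, rcl_start, rcl_end, scissile_offset) {
  protein <- as.character(protein)
  L <- nchar(protein)
  if (scissile_offset < 1 || scissile_offset > rcl_end - rcl_start + 1)
    stop("scissile_offset ", scissile_offset, " outside the RCL match")
  p1_abs <- rcl_start + scissile_offset - 1L
  v <- strsplit(toupper(protein), "", fixed = TRUE)[[1]]
  res_at <- function(i) ifelse(i >= 1 & i <= L, v[pmax(pmin(i, L), 1)], NA_character_)
  up <- p1_abs - (15:1 - 1L)         # P15 .. P1
  down <- p1_abs + (1:4)             # P1' .. P4'
  positions <- c(res_at(up), res_at(down))
  names(positions) <- c(paste0("P", 15:1), paste0("P", 1:4, "'"))
  p1 <- positions[["P1"]]
  p1p <- positions[["P1'"]]
  structure(list(positions = positions, p1 = p1, p1_prime = p1p,
                 predicted_class = classify_by_p1(p1, p1p)),
            class = "rcl_annotation")
}

#' Predict target protease class from P1 (and P1')
#'
#' Screening-level rule table (see the rule order in the package
#' documentation above): dual strictly precedes the hydrophobic rule, so V/I
#' with a small P1' is never labeled `inflammation_control`. Vectorized; a
#' missing or non-standard P1 yields `unknown`.
#'
#' @param p1 P1 residue(s), single letters.
#' @param p1_prime P1' residue(s) or NA when unavailable.
#' @return Character vector over
#'   `{coagulation_complement, inflammation_control, tissue_protection, dual,
#'   unknown}`.
#' @export
classify_by_p1 <- function(p1, p1_prime = NA_character_) {
  p1 <- toupper(as.character(p1))
  p1p <- toupper(as.character(p1_prime))
  if (length(p1p) == 1 && length(p1) > 1) p1p <- rep(p1p, length(p1))
  small_prime <- !is.na(p1p) & p1p %in% c("A", "S", "G", "T")
  out <- rep("unknown", length(p1))
  hydrophobic <- !is.na(p1) & p1 %in% c("F", "Y", "W", "L", "I", "V", "M")
  out[hydrophobic] <- "inflammation_control"
  out[!is.na(p1) & p1 %in% c("A", "S", "G")] <- "tissue_protection"
  out[!is.na(p1) & p1 %in% c("R", "K")] <- "coagulation_complement"
  out[!is.na(p1) & p1 %in% c("V", "I") & small_prime] <- "dual"
  out
}

# Keyword map used to bin experimentally confirmed protease targets into the
# same classes as the P1 rules, for concordance flags.
.TARGET_KEYWORDS <- list(
  coagulation_complement = c("thrombin", "factor x", "fxa", "fxia", "fixa",
                             "factor ix", "factor xi", "kallikrein", "trypsin",
                             "plasmin", "complement", "c1s", "c1r", "masp",
                             "factor i", "c2"),
  inflammation_control = c("cathepsin g", "chymase", "chymotrypsin"),
  tissue_protection = c("elastase", "proteinase 3", "proteinase-3"))

confirmed_target_classes <- function(targets) {
  t <- tolower(targets)
  names(.TARGET_KEYWORDS)[vapply(.TARGET_KEYWORDS, function(kw)
    any(vapply(kw, grepl, logical(1), x = t, fixed = TRUE)), logical(1))]
}

#' Attach experimentally confirmed targets and concordance flags
#'
#' Confirmed targets are attached verbatim alongside the screening-level
#' predictions. The concordance flag is TRUE when the predicted class matches
#' at least one class implied by the confirmed targets (a `dual` prediction is
#' concordant with either of its two classes); NA when the prediction is
#' `unknown` or no evidence exists.
#'
#' @param loci Atlas data.frame with `serpin_name` and `predicted_class`
#'   columns.
#' @param evidence data.frame with columns `serpin_name`, `confirmed_targets`
#'   (free-text, semicolon/comma separated) and optionally `citation`.
#'   Evidence rows naming unknown serpins are skipped with a warning.
#' @return `loci` with `confirmed_targets` and `concordant` columns.
#' @export
annotate_confirmed_targets <- function(loci, evidence) {
  loci$confirmed_targets <- NA_character_
  loci$concordant <- NA
  if (is.null(evidence) || nrow(evidence) == 0) return(loci)
  unknown <- !evidence$serpin_name %in% loci$serpin_name
  if (any(unknown)) {
    warning("evidence for unknown serpin(s) skipped: ",
            paste(evidence$serpin_name[unknown], collapse = ", "))
    evidence <- evidence[!unknown, , drop = FALSE]
  }
  for (i in seq_len(nrow(evidence))) {
    j <- which(loci$serpin_name == evidence$serpin_name[i])
    loci$confirmed_targets[j] <- evidence$confirmed_targets[i]
    classes <- confirmed_target_classes(evidence$confirmed_targets[i])
    pred <- loci$predicted_class[j]
    loci$concordant[j] <- vapply(pred, function(p) {
      if (is.na(p) || p == "unknown" || !length(classes)) return(NA)
      if (p == "dual")
        return(any(c("inflammation_control", "tissue_protection") %in% classes))
      p %in% classes
    }, logical(1))
  }
  loci
}

#' Classify every atlas locus from its RCL
#'
#' Applies [number_rcl()] / [classify_by_p1()] across the atlas, taking each
#' locus's scissile-bond position from the seed-RCL metadata (column
#' `p1_offset` of `seed_info`, the 1-based P1 position within the seed, which
#' is propagated to hits by alignment position since matches are ungapped).
#'
#' @param atlas Atlas data.frame with `protein_id`, `rcl_query`, `rcl_start`,
#'   `rcl_end` columns.
#' @param proteins Named character vector / `AAStringSet`.
#' @param seed_info data.frame with columns `id` and `p1_offset`.
#' @return `atlas` with `p1`, `p1_prime`, `predicted_class` columns. All
#'   predictions are screening-level.
#' @export
classify_atlas_rcl <- function(atlas, proteins, seed_info) {
  prot <- as_named_character(proteins)
  off <- seed_info$p1_offset[match(atlas$rcl_query, seed_info$id)]
  if (anyNA(off))
    stop("no p1_offset metadata for seed(s): ",
         paste(unique(atlas$rcl_query[is.na(off)]), collapse = ", "))
  ann <- lapply(seq_len(nrow(atlas)), function(i)
    number_rcl(prot[[atlas$protein_id[i]]], atlas$rcl_start[i],
               atlas$rcl_end[i], off[i]))
  atlas$p1 <- vapply(ann, function(a) a$p1, character(1))
  atlas$p1_prime <- vapply(ann, function(a) a$p1_prime, character(1))
  atlas$predicted_class <- vapply(ann, function(a) a$predicted_class, character(1))
  atlas
}
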