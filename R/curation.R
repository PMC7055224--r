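.metal_symbols <- c(
  "Li", "Be", "Na", "Mg", "Al", "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn", "Fe",
  "Co", "Ni", "Cu", "Zn", "Ga", "Rb", "Sr", "Y", "Zr", "Nb", "Mo", "Ru", "Rh",
  "Pd", "Ag", "Cd", "In", "Sn", "Sb", "Cs", "Ba", "La", "Ce", "Hf", "Ta", "W",
  "Re", "Os", "Ir", "Pt", "Au", "Hg", "Tl", "Pb", "Bi"
)

# Canonical forms of common organic counterions/solvent adducts: these do not
# count as mixture components and are stripped like inorganic salts.
.salt_organics <- c(
  "CC(=O)O", "CC(=O)[O-]",            # acetate
  "OC=O", "[O-]C=O", "O=CO",          # formate
  "OC(=O)C(=O)O",                     # oxalate
  "CS(=O)(=O)O", "CS(=O)(=O)[O-]",    # methanesulfonate
  "OC(=O)C(F)(F)F",                   # trifluoroacetate
  "OC(=O)C=CC(=O)O",                  # maleate/fumarate (stereo stripped)
  "OC(=O)C(O)C(O)C(=O)O",             # tartrate
  "OC(=O)CC(O)(CC(=O)O)C(=O)O",       # citrate
  "CO",                               # methanol (solvate)
  "CC(C)=O"                           # acetone (solvate)
)

.ob_canonical <- function(smiles) {
  out <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", smiles)),
    error = function(e) ""
  )
  trimws(out)
}

# Tokenize a SMILES fragment into element symbols (heavy atoms only).
.fragment_elements <- function(frag) {
  toks <- regmatches(frag, gregexpr(
    "\\[[^\\]]+\\]|Cl|Br|Si|Se|[BCNOPSFI]|[bcnops]", frag))[[1]]
  els <- vapply(toks, function(t) {
    if (startsWith(t, "[")) {
      m <- regmatches(t, regexpr("[A-Za-z][a-z]?", t))
      el <- if (length(m)) m else ""
      if (el %in% c("c", "n", "o", "p", "s", "b")) el <- toupper(el)
      el
    } else if (t %in% c("c", "n", "o", "p", "s", "b")) toupper(t) else t
  }, character(1))
  els[els != "H" & els != ""]
}

#' Curate a chemical structure from its SMILES
#'
#' Standardizes an input structure for descriptor computation: whitespace and
#' explicit-hydrogen cleanup, sanitization via canonicalization, textual
#' disconnection of singly-bonded metals, stereochemistry stripping,
#' desolvation and removal of salt fragments (inorganic counterions and a
#' fixed list of common organic counterions/solvates). Inputs that retain
#' more than one organic fragment after salt stripping are rejected as
#' mixtures; inputs with no organic fragment are rejected as inorganic.
#'
#' @param smiles Character vector of input SMILES.
#' @param chem_id Optional ids (defaults to `chem_1..n`).
#' @return `data.frame` with `chem_id`, `smiles`, `curated_smiles` (`NA`
#'   unless passed), `curation_status` (`"passed"` or `"rejected"`) and
#'   `reason` (`""`, `"parse_error"`, `"mixture"`, `"inorganic"`).
#' @examples
#' \donttest{
#' curate_structure(c("c1ccccc1", "CC(=O)O.[Na+]", "CCO.CCCCO"))
#' }
#' @export
curate_structure <- function(smiles, chem_id = paste0("chem_", seq_along(smiles))) {
  stopifnot(length(smiles) == length(chem_id))
  res <- lapply(smiles, .curate_one)
  data.frame(
    chem_id = chem_id, smiles = smiles,
    curated_smiles = vapply(res, `[[`, character(1), "curated"),
    curation_status = vapply(res, `[[`, character(1), "status"),
    reason = vapply(res, `[[`, character(1), "reason"),
    stringsAsFactors = FALSE
  )
}

.curate_one <- function(s) {
  rejected <- function(why) list(curated = NA_character_, status = "rejected", reason = why)
  s <- trimws(s)
  if (is.na(s) || !nzchar(s)) return(rejected("parse_error"))

  # stereochemistry stripping (bond direction and tetrahedral marks)
  s <- gsub("[/\\\\]", "", s)
  s <- gsub("@", "", s, fixed = TRUE)
  # disconnect singly-bonded metals written covalently, e.g. O[Na] -> O.[Na]
  pat <- paste0("(\\[(?:", paste(.metal_symbols, collapse = "|"), ")[0-9+-]*\\])")
  s <- gsub(pat, ".\\1.", s)
  s <- gsub("\\.{2,}", ".", s)
  s <- gsub("^\\.|\\.$", "", s)

  can <- .ob_canonical(s)
  if (!nzchar(can)) return(rejected("parse_error"))

  frags <- strsplit(can, ".", fixed = TRUE)[[1]]
  frags <- frags[nzchar(frags)]
  els <- lapply(frags, .fragment_elements)
  organic <- vapply(els, function(e) "C" %in% e, logical(1))
  if (!any(organic)) return(rejected("inorganic"))

  org <- frags[organic]
  if (length(org) > 1L) {
    salt_can <- vapply(.salt_organics, .ob_canonical, character(1))
    is_salt <- vapply(org, function(f) .ob_canonical(f) %in% salt_can, logical(1))
    # keep non-salt organics; if everything matched the salt list keep the largest
    org <- if (all(is_salt)) org[which.max(nchar(org))] else org[!is_salt]
  }
  if (length(org) > 1L) return(rejected("mixture"))

  final <- .ob_canonical(org)
  if (!nzchar(final)) return(rejected("parse_error"))
  # organometallics surviving disconnection (ring/multi-bonded metal) are rejected
  if (any(.fragment_elements(final) %in% .metal_symbols)) return(rejected("inorganic"))
  list(curated = final, status = "passed", reason = "")
}
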