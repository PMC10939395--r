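#' Default lineage keyword table
#'
#' Keyword lookup used to flag ASVs as members of excluded groups (bacteria,
#' metazoans, fungi, macroalgae) or as chloroplast-containing lineages.
#' Matching is case-insensitive against every rank label of a lineage; an
#' excluded-group match always wins over a plastid match. The table is a
#' plain tibble so it can be edited or replaced wholesale: the keyword list
#' is a curatorial choice, not a fixed fact about the groups.
#'
#' @return A tibble with columns `keyword` and `group`
#'   (`"excluded"` or `"plastid"`).
#' @examples
#' default_lineage_keywords()
#' @export
default_lineage_keywords <- function() {
  tibble::tribble(
    ~keyword,              ~group,
    "bacteria",            "excluded",
    "archaea",             "excluded",
    "metazoa",             "excluded",
    "animalia",            "excluded",
    "arthropoda",          "excluded",
    "craniata",            "excluded",
    "fungi",               "excluded",
    "phaeophyceae",        "excluded",
    "ulvophyceae",         "excluded",
    "florideophycidae",    "excluded",
    "bangiophyceae",       "excluded",
    "dinophyceae",         "plastid",
    "dinoflagellata",      "plastid",
    "cryptophyceae",       "plastid",
    "cryptomonadales",     "plastid",
    "chrysophyceae",       "plastid",
    "haptophyta",          "plastid",
    "prymnesiophyceae",    "plastid",
    "chlorophyta",         "plastid",
    "chlorophyceae",       "plastid",
    "trebouxiophyceae",    "plastid",
    "mamiellophyceae",     "plastid",
    "bacillariophyta",     "plastid",
    "bacillariophyceae",   "plastid",
    "coscinodiscophyceae", "plastid",
    "mediophyceae",        "plastid",
    "diatomea",            "plastid",
    "raphidophyceae",      "plastid",
    "dictyochophyceae",    "plastid",
    "pelagophyceae",       "plastid",
    "euglenida",           "plastid"
  )
}

# Tokens that qualify but never name a genus in Silva-style species labels.
GENUS_QUALIFIERS <- c(
  "sp", "spp", "cf", "aff", "uncultured", "unidentified", "unknown",
  "eukaryote", "eukaryotes", "eukaryota", "dinoflagellate", "marine",
  "alveolate", "freshwater", "environmental", "sample", "clone", "strain",
  "protist", "organism"
)

# Suffixes of supra-generic rank names (class, order, family, ...).
RANK_SUFFIX_RE <- "(phyceae|phycidae|phyta|phytina|mycota|mycetes|monadales|ales|aceae|ineae|idae|oidea|idea|phora|poda|zoa)$"

#' Extract a genus label from a taxon name
#'
#' Takes the first token of a binomial, "Genus sp."-style or
#' "Genus uncultured ..." label after stripping qualifier tokens
#' (sp., spp., cf., uncultured, eukaryote, marine, alveolate, freshwater,
#' ...). Labels that only resolve to a class/order/family-level name (for
#' example "dinophyceae uncultured eukaryote" or "Cryptomonadales") yield
#' `NA`: an unresolvable genus is a result, not an error.
#'
#' @param label Character vector of taxon labels.
#' @return Character vector of genus names (first letter capitalized) or
#'   `NA_character_` where no genus is resolvable.
#' @examples
#' extract_genus(c(
#'   "Heterocapsa rotundata",
#'   "Teleaulax uncultured marine eukaryote",
#'   "dinophyceae uncultured eukaryote"
#' ))
#' @export
extract_genus <- function(label) {
  vapply(as.character(label), extract_genus_one, character(1), USE.NAMES = FALSE)
}

extract_genus_one <- function(label) {
  if (is.na(label) || !nzchar(trimws(label))) return(NA_character_)
  tokens <- stringr::str_split_1(trimws(label), "\\s+")
  tokens <- stringr::str_remove_all(tokens, "[.,;:]+$")
  keep <- !(stringr::str_to_lower(tokens) %in% GENUS_QUALIFIERS) & nzchar(tokens)
  tokens <- tokens[keep]
  if (length(tokens) == 0) return(NA_character_)
  first <- tokens[[1]]
  if (nchar(first) < 3) return(NA_character_)
  if (stringr::str_detect(stringr::str_to_lower(first), RANK_SUFFIX_RE)) {
    return(NA_character_)
  }
  # genus names are alphabetic; codes like "GSSW10" are not genera
  if (!stringr::str_detect(first, "^[A-Za-z-]+$")) return(NA_character_)
  paste0(toupper(substr(first, 1, 1)), tolower(substr(first, 2, nchar(first))))
}

#' Split a Silva-style lineage string into rank labels
#'
#' Handles plain semicolon-joined lineages as well as QIIME-style
#' `D_0__`/`d__` rank prefixes; empty and "Ambiguous_taxa" ranks are dropped.
#'
#' @param lineage Character vector of lineage strings.
#' @return A list of character vectors, one per input.
#' @export
split_lineage <- function(lineage) {
  lapply(as.character(lineage), function(x) {
    if (is.na(x) || !nzchar(trimws(x))) return(character(0))
    ranks <- stringr::str_split_1(x, ";")
    ranks <- stringr::str_remove(trimws(ranks), "^[Dd]_\\d+__|^[a-z]__")
    ranks <- trimws(ranks)
    ranks[nzchar(ranks) & ranks != "Ambiguous_taxa" & ranks != "__"]
  })
}

lineage_genus_one <- function(ranks) {
  # genus information, if present, sits in the deepest one or two ranks
  for (r in rev(utils::tail(ranks, 2))) {
    g <- extract_genus_one(r)
    if (!is.na(g)) return(g)
  }
  NA_character_
}

#' Annotate taxonomy assignments with genus and group flags
#'
#' Adds `genus` (via [extract_genus()] on the deepest ranks), `has_plastid`
#' and `is_excluded_group` columns to a taxonomy table. Flags are set by
#' case-insensitive keyword matching of every rank label against a lineage
#' keyword table; an excluded-group match suppresses the plastid flag, so
#' the two flags are never both `TRUE`.
#'
#' @param taxonomy A data frame with columns `asv_id` and `lineage`.
#' @param keywords Keyword table as in [default_lineage_keywords()].
#' @return A tibble with columns `asv_id`, `lineage`, `genus`,
#'   `is_excluded_group`, `has_plastid`.
#' @export
annotate_taxonomy <- function(taxonomy, keywords = default_lineage_keywords()) {
  stopifnot(all(c("asv_id", "lineage") %in% names(taxonomy)))
  if (anyDuplicated(taxonomy$asv_id) > 0) {
    abort("duplicate asv_id in taxonomy table", class = "cmtracer_value_error")
  }
  excl_kw <- stringr::str_to_lower(keywords$keyword[keywords$group == "excluded"])
  plas_kw <- stringr::str_to_lower(keywords$keyword[keywords$group == "plastid"])
  ranks_list <- split_lineage(taxonomy$lineage)
  hit <- function(low, kw) {
    any(vapply(kw, function(k) any(stringr::str_detect(low, stringr::fixed(k))),
               logical(1)))
  }
  flags <- purrr::map(ranks_list, function(ranks) {
    low <- stringr::str_to_lower(ranks)
    excl <- hit(low, excl_kw)
    list(
      genus = lineage_genus_one(ranks),
      is_excluded_group = excl,
      has_plastid = !excl && hit(low, plas_kw)
    )
  })
  tibble::tibble(
    asv_id = as.character(taxonomy$asv_id),
    lineage = as.character(taxonomy$lineage),
    genus = purrr::map_chr(flags, "genus"),
    is_excluded_group = purrr::map_lgl(flags, "is_excluded_group"),
    has_plastid = purrr::map_lgl(flags, "has_plastid")
  )
}
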