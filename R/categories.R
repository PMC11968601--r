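#' The ten structured-report categories
#'
#' Breast MRI reports are structured into a fixed template of ten categories
#' drawn from the standard MRI imaging lexicon: fibroglandular tissue amount,
#' background parenchymal enhancement, mass/non-mass, axillary lymph nodes,
#' skin lesions, non-enhancing findings, associated findings, fat-containing
#' lesions, dynamic contrast-enhanced (DCE) curve assessment, and prosthesis.
#' The order returned here is the canonical serialization order used
#' everywhere in the package (JSONL output, structured-text rendering,
#' tie-breaking in term routing).
#'
#' @return Character vector of the ten category identifiers, in canonical
#'   order.
#' @export
#' @examples
#' category_names()
category_names <- function() {
  c(
    "amount_of_fibroglandular_tissue",
    "background_parenchymal_enhancement",
    "mass_non_mass",
    "axillary_lymph_nodes",
    "skin_lesions",
    "non_enhancing_findings",
    "associated_findings",
    "fat_containing_lesions",
    "dce_curve_assessment",
    "prosthesis"
  )
}

#' Sentinel descriptor for categories absent from a report
#'
#' Missing category information (MCI) completion assigns this exact string to
#' template categories that the narrative does not mention.
#'
#' @return The string `"not mentioned"` (or its Chinese rendering when
#'   `dialect = "chinese"`).
#' @param dialect `"english"` or `"chinese"`.
#' @export
mci_sentinel <- function(dialect = "english") {
  dialect <- match.arg(dialect, c("english", "chinese"))
  if (dialect == "chinese") "未提及" else "not mentioned"
}

# human-readable display name, used in structured-text rendering and prompts
category_display <- function(x) gsub("_", " ", x, fixed = TRUE)

#' Load a category lexicon
#'
#' A lexicon maps each of the ten categories to a short definition and a
#' non-empty list of allowed descriptor terms. The lexicon shipped with the
#' package (`inst/extdata/lexicon.yaml`) is a synthetic stand-in assembled
#' from standard BI-RADS descriptor vocabulary (kinetic curve types, margin
#' and shape terms, nodal descriptors); it is data, not code, so users with
#' access to the full fifth-edition MRI lexicon can substitute their own file
#' with the same layout.
#'
#' @param path Path to a YAML (or JSON) file mapping
#'   `category -> {definition, terms}`. Defaults to the shipped stand-in.
#' @return A named list of `list(definition =, terms =)` entries, one per
#'   category, in canonical order, with class `"birads_lexicon"`.
#' @export
read_lexicon <- function(path = system.file("extdata", "lexicon.yaml",
                                            package = "biradsfusion")) {
  raw <- yaml::read_yaml(path)
  validate_lexicon(raw)
}

#' @rdname read_lexicon
#' @export
default_lexicon <- function() {
  lex <- get0(".default_lexicon", envir = .biradsfusion_cache)
  if (is.null(lex)) {
    lex <- read_lexicon()
    assign(".default_lexicon", lex, envir = .biradsfusion_cache)
  }
  lex
}

.biradsfusion_cache <- new.env(parent = emptyenv())

validate_lexicon <- function(lex) {
  cats <- category_names()
  missing <- setdiff(cats, names(lex))
  if (length(missing) > 0L) {
    stop("lexicon is missing categories: ", paste(missing, collapse = ", "))
  }
  extra <- setdiff(names(lex), cats)
  if (length(extra) > 0L) {
    stop("lexicon has unknown categories: ", paste(extra, collapse = ", "))
  }
  lex <- lex[cats]
  for (cat in cats) {
    entry <- lex[[cat]]
    if (is.null(entry$definition) || !nzchar(entry$definition)) {
      stop("lexicon category '", cat, "' has no definition")
    }
    terms <- unlist(entry$terms)
    if (length(terms) == 0L || any(!nzchar(terms))) {
      stop("lexicon category '", cat, "' needs a non-empty term list")
    }
    lex[[cat]]$terms <- as.character(terms)
  }
  structure(lex, class = "birads_lexicon")
}

#' @export
print.birads_lexicon <- function(x, ...) {
  cat("<birads_lexicon> 10 categories\n")
  for (cat_name in names(x)) {
    cat(sprintf("  %-36s %d terms\n", cat_name, length(x[[cat_name]]$terms)))
  }
  invisible(x)
}
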