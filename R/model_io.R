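#' Read a stoichiometric model from a tab-delimited file
#'
#' The TSV dialect is one reaction per line,
#' `id<TAB>equation<TAB>reversible{0,1}<TAB>genes(comma-separated)`,
#' with equations written `2 A + B -> C` (`<->` for reversible; one side may
#' be empty for uptake/excretion or deliberately unbalanced products).
#' Metabolites suffixed `_ext` are external (unbalanced); all others are
#' internal. Designated reactions are declared in header lines
#' `#substrate<TAB>id`, `#product<TAB>id`, `#biomass<TAB>id`. Molecular
#' weights come from a separate CSV (see [read_mw()]) or the `mw` argument.
#'
#' @param path Path to the model file.
#' @param format `"tsv"` (the dialect above) or `"sbml"` (level-3 core;
#'   stoichiometry and reversibility only, designations via `mw`/arguments).
#' @param mw Optional named numeric vector of molecular weights (g/mol).
#' @param substrate,product,biomass Designated reaction ids; for TSV these
#'   default to the header declarations and only need to be given for SBML.
#' @param name Model label; defaults to the file name.
#' @return A validated [stoich_model()].
#' @export
read_model <- function(path, format = c("tsv", "sbml"), mw = numeric(),
                       substrate = NULL, product = NULL, biomass = NULL,
                       name = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("model file not found: ", path, call. = FALSE)
  if (is.null(name)) name <- basename(path)
  if (format == "sbml") {
    return(read_model_sbml(path, mw = mw, substrate = substrate,
                           product = product, biomass = biomass, name = name))
  }

  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines, which = "right")
  lines <- lines[nzchar(lines)]

  header <- list()
  for (ln in grep("^#", lines, value = TRUE)) {
    parts <- strsplit(sub("^#", "", ln), "\t", fixed = TRUE)[[1]]
    if (length(parts) >= 2 && parts[1] %in% c("substrate", "product", "biomass")) {
      header[[parts[1]]] <- parts[2]
    }
  }
  body <- grep("^#", lines, value = TRUE, invert = TRUE)
  if (length(body) == 0L) stop("model file has an empty reaction list", call. = FALSE)

  rows <- lapply(body, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 2) stop("malformed model line: ", ln, call. = FALSE)
    eq <- parse_reaction_equation(f[2], rxn_id = f[1])
    rev_flag <- if (length(f) >= 3 && nzchar(f[3])) f[3] == "1" else eq$reversible
    genes <- if (length(f) >= 4 && nzchar(f[4])) {
      trimws(strsplit(f[4], ",", fixed = TRUE)[[1]])
    } else character()
    list(id = f[1], stoich = eq$stoich, reversible = rev_flag | eq$reversible,
         genes = genes)
  })

  met_ids <- unique(unlist(lapply(rows, function(r) names(r$stoich))))
  metabolites <- tibble::tibble(
    id = met_ids,
    name = met_ids,
    is_internal = !grepl("_ext$", met_ids)
  )
  reactions <- tibble::tibble(
    id = vapply(rows, `[[`, "", "id"),
    reversible = vapply(rows, `[[`, TRUE, "reversible"),
    genes = lapply(rows, `[[`, "genes"),
    stoichiometry = lapply(rows, `[[`, "stoich")
  )

  substrate <- substrate %||% header$substrate
  product <- product %||% header$product
  biomass <- biomass %||% header$biomass
  if (is.null(substrate) || is.null(product) || is.null(biomass)) {
    stop("model file must designate #substrate, #product and #biomass reactions",
         call. = FALSE)
  }
  stoich_model(metabolites, reactions, substrate, product, biomass,
               mw = mw, name = name)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Parse a reaction equation string
#'
#' Accepts `2 A + B -> C`, `A <-> B`, and one-sided equations such as
#' `GLC_ext ->` . Coefficients default to 1 and may be decimal.
#'
#' @param eq Equation string.
#' @param rxn_id Reaction id used in error messages.
#' @return A list with `stoich` (named numeric, products positive) and
#'   `reversible` (logical, `TRUE` for `<->`).
#' @keywords internal
parse_reaction_equation <- function(eq, rxn_id = "?") {
  reversible <- grepl("<->", eq, fixed = TRUE)
  sides <- strsplit(eq, if (reversible) "<->" else "->", fixed = TRUE)[[1]]
  if (length(sides) == 1L) sides <- c(sides, "")
  if (length(sides) != 2L || !grepl("->", eq, fixed = TRUE)) {
    stop("reaction '", rxn_id, "': cannot parse equation '", eq, "'",
         call. = FALSE)
  }
  parse_side <- function(side, sign) {
    side <- trimws(side)
    if (!nzchar(side)) return(numeric())
    terms <- trimws(strsplit(side, "+", fixed = TRUE)[[1]])
    out <- numeric()
    for (tm in terms[nzchar(terms)]) {
      m <- regmatches(tm, regexec("^([0-9]*\\.?[0-9]+[eE]?-?[0-9]*\\s+)?([A-Za-z_][A-Za-z0-9_]*)$", tm))[[1]]
      if (length(m) == 0L) {
        stop("reaction '", rxn_id, "': cannot parse term '", tm, "'",
             call. = FALSE)
      }
      coef <- if (nzchar(trimws(m[2]))) as.numeric(trimws(m[2])) else 1
      met <- m[3]
      out[met] <- (out[met] %||NA% 0) + sign * coef
    }
    out
  }
  `%||NA%` <- function(a, b) if (length(a) == 0 || is.na(a)) b else a
  lhs <- parse_side(sides[1], -1)
  rhs <- parse_side(sides[2], +1)
  st <- lhs
  for (met in names(rhs)) st[met] <- (if (met %in% names(st)) st[met] else 0) + rhs[met]
  st <- st[st != 0]
  list(stoich = st, reversible = reversible)
}

#' Serialize a model to the package's TSV dialect
#'
#' Round-trips with [read_model()]: designations, reversibility, internal /
#' external flags and coefficients are preserved.
#'
#' @param model A [stoich_model()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  fmt_side <- function(st) {
    paste(vapply(names(st), function(m) {
      if (abs(st[[m]] - 1) < 1e-12) m else paste(format(st[[m]], digits = 12), m)
    }, ""), collapse = " + ")
  }
  lines <- c(
    paste0("#substrate\t", model$substrate_rxn),
    paste0("#product\t", model$product_rxn),
    paste0("#biomass\t", model$biomass_rxn)
  )
  for (i in seq_len(nrow(model$reactions))) {
    st <- model$reactions$stoichiometry[[i]]
    lhs <- -st[st < 0]
    rhs <- st[st > 0]
    arrow <- if (model$reactions$reversible[i]) "<->" else "->"
    eq <- trimws(paste(fmt_side(lhs), arrow, fmt_side(rhs)))
    lines <- c(lines, paste(model$reactions$id[i], eq,
                            as.integer(model$reactions$reversible[i]),
                            paste(model$reactions$genes[[i]], collapse = ","),
                            sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read molecular weights from CSV
#'
#' Expected columns: `species,mw_g_per_mol`.
#'
#' @param path CSV path.
#' @return Named numeric vector (g/mol).
#' @export
read_mw <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("species", "mw_g_per_mol") %in% names(tab))) {
    stop("molecular weight CSV needs columns species,mw_g_per_mol", call. = FALSE)
  }
  stats::setNames(tab$mw_g_per_mol, tab$species)
}

# Minimal SBML level-3 core reader: species, reactions (stoichiometry +
# reversibility). Boundary-condition / compartment "ext" species are external.
read_model_sbml <- function(path, mw, substrate, product, biomass, name) {
  doc <- xml2::read_xml(path)
  ns <- c(s = xml2::xml_ns(doc)[[1]])
  species <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  sp_id <- xml2::xml_attr(species, "id")
  boundary <- xml2::xml_attr(species, "boundaryCondition") %in% c("true", "1") |
    grepl("_ext$", sp_id)
  metabolites <- tibble::tibble(
    id = sp_id,
    name = ifelse(is.na(xml2::xml_attr(species, "name")), sp_id,
                  xml2::xml_attr(species, "name")),
    is_internal = !boundary
  )
  rxn_nodes <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  rows <- lapply(rxn_nodes, function(nd) {
    get_refs <- function(which, sign) {
      refs <- xml2::xml_find_all(nd, paste0("./s:", which, "/s:speciesReference"), ns)
      if (length(refs) == 0L) return(numeric())
      coef <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
      coef[is.na(coef)] <- 1
      stats::setNames(sign * coef, xml2::xml_attr(refs, "species"))
    }
    st <- c(get_refs("listOfReactants", -1), get_refs("listOfProducts", +1))
    st <- tapply(st, names(st), sum)
    st <- stats::setNames(as.numeric(st), names(st))
    list(id = xml2::xml_attr(nd, "id"),
         reversible = xml2::xml_attr(nd, "reversible") %in% c("true", "1"),
         stoich = st[st != 0])
  })
  reactions <- tibble::tibble(
    id = vapply(rows, `[[`, "", "id"),
    reversible = vapply(rows, `[[`, TRUE, "reversible"),
    genes = rep(list(character()), length(rows)),
    stoichiometry = lapply(rows, `[[`, "stoich")
  )
  if (is.null(substrate) || is.null(product) || is.null(biomass)) {
    stop("SBML input carries no reaction designations; pass substrate=, ",
         "product= and biomass=", call. = FALSE)
  }
  stoich_model(metabolites, reactions, substrate, product, biomass,
               mw = mw, name = name)
}
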