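#' @title Model input/output
#' @description Readers and writers for COBRA-style JSON and SBML Level 3
#'   FBC models, plus the medium format. Unbounded flux bounds are mapped
#'   to a finite global cap on read (the usual COBRA +/-1000 convention).
#' @name model-io
NULL

.default_biomass_patterns <- c("biomass")

# Decide the biomass reaction: explicit objective first, then
# case-insensitive id/name pattern match, then the caller's override.
.detect_biomass <- function(rxns, objective_ids, biomass_reaction_id,
                            biomass_patterns) {
  if (!is.null(biomass_reaction_id)) {
    if (!biomass_reaction_id %in% rxns$id) {
      stop("biomass_reaction_id '", biomass_reaction_id, "' not in model")
    }
    return(biomass_reaction_id)
  }
  if (length(objective_ids) && objective_ids[1L] %in% rxns$id) {
    return(objective_ids[1L])
  }
  for (pat in biomass_patterns) {
    hit <- grepl(pat, rxns$id, ignore.case = TRUE) |
      grepl(pat, rxns$name, ignore.case = TRUE)
    if (any(hit)) return(rxns$id[which(hit)[1L]])
  }
  NA_character_
}

.clip_bounds <- function(x, cap) pmin(pmax(x, -cap), cap)

#' Read a metabolic model from file
#'
#' Supports COBRA-style JSON and SBML Level 3 with the FBC package.
#' Flux bounds beyond the global cap (including infinities) are clipped
#' to `+/-flux_cap`. The biomass reaction is taken from the model
#' objective, falling back to a case-insensitive id/name pattern match,
#' or to `biomass_reaction_id` when supplied.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"cobra-json"`, or `"sbml-fbc"`.
#' @param flux_cap finite bound replacing infinities (default 1000).
#' @param biomass_reaction_id optional explicit biomass reaction id.
#' @param biomass_patterns patterns tried when no objective is declared.
#' @param require_biomass error when no biomass reaction can be
#'   identified (default `TRUE`; databases are read with `FALSE`).
#' @return a [metabolic_model].
#' @export
read_model <- function(path, format = c("auto", "cobra-json", "sbml-fbc"),
                       flux_cap = 1000,
                       biomass_reaction_id = NULL,
                       biomass_patterns = .default_biomass_patterns,
                       require_biomass = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("model file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) {
      "sbml-fbc"
    } else "cobra-json"
  }
  m <- switch(format,
              "cobra-json" = .read_cobra_json(path),
              "sbml-fbc" = .read_sbml_fbc(path))
  m$rxns$lb <- .clip_bounds(m$rxns$lb, flux_cap)
  m$rxns$ub <- .clip_bounds(m$rxns$ub, flux_cap)
  nnz <- Matrix::colSums(m$S != 0)
  m$rxns$is_exchange <- nnz == 1 & grepl("^(EX_|DM_|sink_)", m$rxns$id)
  # single-metabolite reactions with no recognizable prefix still cross
  # the boundary; treat any singleton as exchange
  m$rxns$is_exchange <- m$rxns$is_exchange | nnz == 1
  bid <- .detect_biomass(m$rxns, m$objective_ids, biomass_reaction_id,
                         biomass_patterns)
  if (is.na(bid) && require_biomass) {
    stop("no biomass reaction found in '", path,
         "'; supply biomass_reaction_id")
  }
  m$rxns$is_biomass <- !is.na(bid) & m$rxns$id == bid
  # a biomass drain may touch a single pseudo-metabolite; it is never
  # an exchange reaction
  m$rxns$is_exchange <- m$rxns$is_exchange & !m$rxns$is_biomass
  metabolic_model(m$id, m$mets, m$rxns, m$S, bid)
}

.read_cobra_json <- function(path) {
  j <- tryCatch(jsonlite::read_json(path),
                error = function(e) stop("JSON parse failure in '", path,
                                         "': ", conditionMessage(e)))
  if (is.null(j$metabolites) || is.null(j$reactions)) {
    stop("not a COBRA JSON model (missing metabolites/reactions): ", path)
  }
  g <- function(x, f, d) if (is.null(x[[f]]) || length(x[[f]]) == 0) d else x[[f]]
  mets <- do.call(rbind, lapply(j$metabolites, function(x) {
    data.frame(id = x$id, name = g(x, "name", x$id),
               formula = as.character(g(x, "formula", NA_character_)),
               charge = as.numeric(g(x, "charge", NA_real_)),
               compartment = as.character(g(x, "compartment", NA_character_)),
               stringsAsFactors = FALSE)
  }))
  nr <- length(j$reactions)
  rid <- character(nr); rname <- character(nr)
  lb <- numeric(nr); ub <- numeric(nr); objc <- numeric(nr)
  trip <- vector("list", nr)
  for (k in seq_len(nr)) {
    x <- j$reactions[[k]]
    rid[k] <- x$id; rname[k] <- g(x, "name", x$id)
    lb[k] <- as.numeric(g(x, "lower_bound", -1000))
    ub[k] <- as.numeric(g(x, "upper_bound", 1000))
    objc[k] <- as.numeric(g(x, "objective_coefficient", 0))
    st <- x$metabolites
    if (length(st)) {
      miss <- setdiff(names(st), mets$id)
      if (length(miss)) {
        stop("reaction '", x$id, "' references undeclared metabolite(s): ",
             paste(miss, collapse = ", "))
      }
      trip[[k]] <- data.frame(i = match(names(st), mets$id), j = k,
                              x = as.numeric(unlist(st)))
    }
  }
  tr <- do.call(rbind, trip)
  S <- Matrix::sparseMatrix(i = tr$i, j = tr$j, x = tr$x,
                            dims = c(nrow(mets), nr))
  rxns <- data.frame(id = rid, name = rname, lb = lb, ub = ub,
                     stringsAsFactors = FALSE)
  list(id = if (!is.null(j$id)) j$id else basename(path),
       mets = mets, rxns = rxns, S = S,
       objective_ids = rid[objc != 0])
}

.strip_sbml_prefix <- function(x, prefix) sub(paste0("^", prefix), "", x)

.read_sbml_fbc <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("SBML parse failure in '", path,
                                           "': ", conditionMessage(e)))
  ln <- function(node, name) {
    xml2::xml_find_all(node, sprintf(".//*[local-name()='%s']", name))
  }
  attr_by_suffix <- function(node, suffix) {
    a <- xml2::xml_attrs(node)
    hit <- grep(paste0("(^|:)", suffix, "$"), names(a))
    if (length(hit)) a[[hit[1L]]] else NA_character_
  }
  mdl <- ln(doc, "model")
  if (length(mdl) == 0L) stop("no <model> element in '", path, "'")
  mdl <- mdl[[1L]]
  model_id <- xml2::xml_attr(mdl, "id")
  if (is.na(model_id)) model_id <- basename(path)

  params <- ln(mdl, "parameter")
  pval <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                          xml2::xml_attr(params, "id"))

  sp <- ln(mdl, "species")
  boundary <- xml2::xml_attr(sp, "boundaryCondition") %in% "true"
  sp <- sp[!boundary]
  mets <- data.frame(
    id = .strip_sbml_prefix(xml2::xml_attr(sp, "id"), "M_"),
    name = xml2::xml_attr(sp, "name"),
    formula = vapply(sp, attr_by_suffix, "", suffix = "chemicalFormula"),
    charge = as.numeric(vapply(sp, attr_by_suffix, "", suffix = "charge")),
    compartment = xml2::xml_attr(sp, "compartment"),
    stringsAsFactors = FALSE)
  mets$name[is.na(mets$name)] <- mets$id[is.na(mets$name)]

  rx <- ln(mdl, "reaction")
  nr <- length(rx)
  rid <- .strip_sbml_prefix(xml2::xml_attr(rx, "id"), "R_")
  rname <- xml2::xml_attr(rx, "name"); rname[is.na(rname)] <- rid[is.na(rname)]
  lb <- numeric(nr); ub <- numeric(nr); trip <- vector("list", nr)
  for (k in seq_len(nr)) {
    node <- rx[[k]]
    lbp <- attr_by_suffix(node, "lowerFluxBound")
    ubp <- attr_by_suffix(node, "upperFluxBound")
    rev <- xml2::xml_attr(node, "reversible") %in% "true"
    lb[k] <- if (!is.na(lbp) && lbp %in% names(pval)) pval[[lbp]] else
      if (rev) -Inf else 0
    ub[k] <- if (!is.na(ubp) && ubp %in% names(pval)) pval[[ubp]] else Inf
    reac <- xml2::xml_find_all(node,
      ".//*[local-name()='listOfReactants']/*[local-name()='speciesReference']")
    prod <- xml2::xml_find_all(node,
      ".//*[local-name()='listOfProducts']/*[local-name()='speciesReference']")
    sref <- function(nodes, sign) {
      if (length(nodes) == 0L) return(NULL)
      sid <- .strip_sbml_prefix(xml2::xml_attr(nodes, "species"), "M_")
      stv <- as.numeric(xml2::xml_attr(nodes, "stoichiometry"))
      stv[is.na(stv)] <- 1
      data.frame(id = sid, x = sign * stv, stringsAsFactors = FALSE)
    }
    st <- rbind(sref(reac, -1), sref(prod, +1))
    if (!is.null(st)) {
      st <- st[st$id %in% mets$id, , drop = FALSE]  # boundary species fall out
      miss <- setdiff(st$id, mets$id)
      if (length(miss)) {
        stop("reaction '", rid[k], "' references undeclared species: ",
             paste(miss, collapse = ", "))
      }
      if (nrow(st)) {
        trip[[k]] <- data.frame(i = match(st$id, mets$id), j = k, x = st$x)
      }
    }
    # referential check against the raw (unfiltered) species list
    raw_ids <- c(xml2::xml_attr(reac, "species"), xml2::xml_attr(prod, "species"))
    all_sp <- xml2::xml_attr(ln(mdl, "species"), "id")
    bad <- setdiff(raw_ids, all_sp)
    if (length(bad)) {
      stop("reaction '", rid[k], "' references undeclared species: ",
           paste(.strip_sbml_prefix(bad, "M_"), collapse = ", "))
    }
  }
  tr <- do.call(rbind, trip)
  S <- Matrix::sparseMatrix(i = tr$i, j = tr$j, x = tr$x,
                            dims = c(nrow(mets), nr))
  fobj <- ln(mdl, "fluxObjective")
  objective_ids <- .strip_sbml_prefix(
    vapply(fobj, function(n) {
      a <- xml2::xml_attrs(n)
      hit <- grep("(^|:)reaction$", names(a))
      if (length(hit)) a[[hit[1L]]] else NA_character_
    }, ""), "R_")
  rxns <- data.frame(id = rid, name = rname, lb = lb, ub = ub,
                     stringsAsFactors = FALSE)
  list(id = model_id, mets = mets, rxns = rxns, S = S,
       objective_ids = objective_ids[!is.na(objective_ids)])
}

#' Write a metabolic model to file
#'
#' @param model a [metabolic_model].
#' @param path output path.
#' @param format `"auto"` (by extension), `"cobra-json"`, or `"sbml-fbc"`.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path,
                        format = c("auto", "cobra-json", "sbml-fbc")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) {
      "sbml-fbc"
    } else "cobra-json"
  }
  switch(format,
         "cobra-json" = .write_cobra_json(model, path),
         "sbml-fbc" = .write_sbml_fbc(model, path))
  invisible(path)
}

.write_cobra_json <- function(model, path) {
  mets <- lapply(seq_len(nrow(model$mets)), function(i) {
    r <- model$mets[i, ]
    out <- list(id = r$id, name = r$name, compartment = r$compartment)
    if (!is.na(r$formula)) out$formula <- r$formula
    if (!is.na(r$charge)) out$charge <- r$charge
    out
  })
  rxns <- lapply(seq_len(nrow(model$rxns)), function(k) {
    r <- model$rxns[k, ]
    st <- reaction_stoichiometry(model, r$id)
    list(id = r$id, name = r$name,
         metabolites = as.list(st),
         lower_bound = r$lb, upper_bound = r$ub,
         objective_coefficient = if (isTRUE(r$is_biomass)) 1 else 0)
  })
  jsonlite::write_json(list(id = model$id, metabolites = mets,
                            reactions = rxns),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

.xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

.write_sbml_fbc <- function(model, path) {
  con <- file(path, open = "wt"); on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w('<?xml version="1.0" encoding="UTF-8"?>')
  w('<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
    'xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" ',
    'level="3" version="1" fbc:required="false">')
  w('  <model id="', .xml_escape(model$id), '" fbc:strict="true">')
  comps <- unique(stats::na.omit(model$mets$compartment))
  if (length(comps) == 0) comps <- "c"
  w('    <listOfCompartments>')
  for (cmp in comps) w('      <compartment id="', cmp, '" constant="true"/>')
  w('    </listOfCompartments>')
  w('    <listOfSpecies>')
  for (i in seq_len(nrow(model$mets))) {
    r <- model$mets[i, ]
    extra <- ""
    if (!is.na(r$formula)) {
      extra <- paste0(extra, ' fbc:chemicalFormula="', r$formula, '"')
    }
    if (!is.na(r$charge)) {
      extra <- paste0(extra, ' fbc:charge="', format(r$charge), '"')
    }
    w('      <species id="M_', r$id, '" name="', .xml_escape(r$name),
      '" compartment="', if (is.na(r$compartment)) comps[1] else r$compartment,
      '" hasOnlySubstanceUnits="false" boundaryCondition="false" ',
      'constant="false"', extra, '/>')
  }
  w('    </listOfSpecies>')
  bounds <- sort(unique(c(model$rxns$lb, model$rxns$ub)))
  bid <- function(v) paste0("P_b", match(v, bounds))
  w('    <listOfParameters>')
  for (v in bounds) {
    w('      <parameter id="', bid(v), '" value="', .lp_num(v),
      '" constant="true"/>')
  }
  w('    </listOfParameters>')
  w('    <listOfReactions>')
  for (k in seq_len(nrow(model$rxns))) {
    r <- model$rxns[k, ]
    st <- reaction_stoichiometry(model, r$id)
    w('      <reaction id="R_', r$id, '" name="', .xml_escape(r$name),
      '" reversible="', tolower(r$lb < 0), '" fast="false" ',
      'fbc:lowerFluxBound="', bid(r$lb), '" fbc:upperFluxBound="',
      bid(r$ub), '">')
    reac <- st[st < 0]; prod <- st[st > 0]
    if (length(reac)) {
      w('        <listOfReactants>')
      for (mi in names(reac)) {
        w('          <speciesReference species="M_', mi, '" stoichiometry="',
          .lp_num(-reac[[mi]]), '" constant="true"/>')
      }
      w('        </listOfReactants>')
    }
    if (length(prod)) {
      w('        <listOfProducts>')
      for (mi in names(prod)) {
        w('          <speciesReference species="M_', mi, '" stoichiometry="',
          .lp_num(prod[[mi]]), '" constant="true"/>')
      }
      w('        </listOfProducts>')
    }
    w('      </reaction>')
  }
  w('    </listOfReactions>')
  if (!is.na(model$biomass_reaction_id)) {
    w('    <fbc:listOfObjectives fbc:activeObjective="obj">')
    w('      <fbc:objective fbc:id="obj" fbc:type="maximize">')
    w('        <fbc:listOfFluxObjectives>')
    w('          <fbc:fluxObjective fbc:reaction="R_',
      model$biomass_reaction_id, '" fbc:coefficient="1"/>')
    w('        </fbc:listOfFluxObjectives>')
    w('      </fbc:objective>')
    w('    </fbc:listOfObjectives>')
  }
  w('  </model>')
  w('</sbml>')
}

#' Read a medium specification
#'
#' A medium gives bounds for the environment exchange of pool
#' metabolites, with uptake negative (COBRA exchange convention). JSON
#' holds `{"default_policy": ..., "bounds": {"glc__D": [-10, 1000]}}`;
#' TSV has columns `base_id`, `lb`, `ub`.
#'
#' @param path JSON or TSV file.
#' @return a [medium].
#' @export
read_medium <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    j <- jsonlite::read_json(path)
    bounds <- lapply(j$bounds, function(x) as.numeric(unlist(x)))
    medium(bounds,
           default_policy = if (is.null(j$default_policy)) {
             "open_secretion_only"
           } else j$default_policy)
  } else {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    medium(stats::setNames(Map(c, tab$lb, tab$ub), tab$base_id))
  }
}

#' Write a medium specification to JSON
#'
#' @param med a [medium].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_medium <- function(med, path) {
  jsonlite::write_json(list(default_policy = med$default_policy,
                            bounds = med$bounds),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
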