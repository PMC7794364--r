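#' Read a metabolic model from disk
#'
#' Three dialects are supported. `"json"` is the primary interchange format
#' (COBRA-style: top-level `metabolites`, `reactions` with a `metabolites`
#' coefficient map, `lower_bound`/`upper_bound`, `gene_reaction_rule`,
#' `objective_coefficient`). `"tsv"` reads a directory holding
#' `metabolites.tsv` and `reactions.tsv` with inline stoichiometry
#' (`met:coef;met:coef`), convenient for hand-written toy models. `"sbml"`
#' is a minimal SBML Level 3 import that understands the FBC bounds and
#' objective and `fbc:geneProductAssociation` rules.
#'
#' @param path File (json, sbml) or directory (tsv).
#' @param format One of `"json"`, `"tsv"`, `"sbml"`; default guesses from the
#'   path.
#' @return A validated [metabolic_model()].
#' @export
read_metabolic_model <- function(path, format = c("auto", "json", "tsv", "sbml")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (dir.exists(path)) "tsv"
      else if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) "sbml"
      else "json"
  }
  if (!file.exists(path)) abort(sprintf("no such file or directory: %s", path))
  switch(format,
    json = read_model_json(path),
    tsv = read_model_tsv(path),
    sbml = read_model_sbml(path)
  )
}

#' Write a metabolic model to disk
#'
#' @param model A `metabolic_model`.
#' @param path Output file (json) or directory (tsv; created if absent).
#' @param format `"json"` (default) or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_metabolic_model <- function(model, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  if (format == "json") {
    rx <- lapply(seq_len(nrow(model$reactions)), function(i) {
      r <- model$reactions[i, ]
      list(
        id = r$id,
        metabolites = as.list(r$stoichiometry[[1]]),
        lower_bound = r$lower_bound,
        upper_bound = r$upper_bound,
        gene_reaction_rule = r$gpr,
        subsystem = if (is.na(r$subsystem)) "" else r$subsystem,
        objective_coefficient =
          if (r$id %in% names(model$objective)) unname(model$objective[r$id]) else 0
      )
    })
    mets <- lapply(seq_len(nrow(model$metabolites)), function(i) {
      m <- model$metabolites[i, ]
      list(id = m$id, name = m$name, compartment = m$compartment)
    })
    jsonlite::write_json(list(id = model$name, metabolites = mets, reactions = rx),
                         path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    utils::write.table(model$metabolites, file.path(path, "metabolites.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    rx <- model$reactions
    rx$stoichiometry <- vapply(rx$stoichiometry, function(st) {
      paste(sprintf("%s:%.12g", names(st), st), collapse = ";")
    }, character(1))
    rx$objective <- ifelse(rx$id %in% names(model$objective),
                           model$objective[rx$id], 0)
    utils::write.table(rx, file.path(path, "reactions.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

read_model_json <- function(path) {
  j <- tryCatch(jsonlite::read_json(path),
                error = function(e) abort(sprintf("JSON parse failure in %s: %s",
                                                  path, conditionMessage(e))))
  for (field in c("metabolites", "reactions")) {
    if (is.null(j[[field]])) abort(sprintf("JSON model %s: missing '%s' element", path, field))
  }
  mets <- dplyr::bind_rows(lapply(j$metabolites, function(m) {
    if (is.null(m$id)) abort(sprintf("JSON model %s: metabolite without id", path))
    tibble(id = m$id,
           name = if (is.null(m$name)) m$id else m$name,
           compartment = if (is.null(m$compartment)) guess_compartment(m$id) else m$compartment)
  }))
  obj <- numeric()
  rxns <- dplyr::bind_rows(lapply(j$reactions, function(r) {
    if (is.null(r$id)) abort(sprintf("JSON model %s: reaction without id", path))
    st <- unlist(r$metabolites)
    oc <- if (is.null(r$objective_coefficient)) 0 else r$objective_coefficient
    if (oc != 0) obj[[r$id]] <<- oc
    tibble(id = r$id,
           stoichiometry = list(st),
           lower_bound = if (is.null(r$lower_bound)) -1000 else r$lower_bound,
           upper_bound = if (is.null(r$upper_bound)) 1000 else r$upper_bound,
           gpr = if (is.null(r$gene_reaction_rule)) "" else r$gene_reaction_rule,
           subsystem = if (is.null(r$subsystem) || !nzchar(r$subsystem)) NA_character_ else r$subsystem)
  }))
  name <- if (!is.null(j$id)) j$id else if (!is.null(j$name)) j$name else basename(path)
  metabolic_model(mets, rxns, objective = obj, name = name)
}

# trailing _x or [x] in a metabolite id, else "c"
guess_compartment <- function(id) {
  m <- regmatches(id, regexpr("(_[a-z]$)|(\\[[a-z]\\]$)", id))
  if (length(m) == 1 && nzchar(m)) gsub("[^a-z]", "", m) else "c"
}

read_model_tsv <- function(path) {
  fm <- file.path(path, "metabolites.tsv")
  fr <- file.path(path, "reactions.tsv")
  for (f in c(fm, fr)) if (!file.exists(f)) abort(sprintf("TSV model: missing %s", f))
  mets <- utils::read.delim(fm, stringsAsFactors = FALSE)
  rx <- utils::read.delim(fr, stringsAsFactors = FALSE)
  need <- setdiff(c("id", "stoichiometry", "lower_bound", "upper_bound"), names(rx))
  if (length(need) > 0) {
    abort(sprintf("reactions.tsv: missing column(s) %s", paste(need, collapse = ", ")))
  }
  st <- lapply(seq_len(nrow(rx)), function(i) {
    s <- rx$stoichiometry[i]
    parts <- strsplit(s, ";", fixed = TRUE)[[1]]
    kv <- strsplit(parts, ":", fixed = TRUE)
    bad <- vapply(kv, length, integer(1)) != 2
    if (any(bad)) {
      abort(sprintf("reactions.tsv line %d ('%s'): cannot parse stoichiometry '%s'",
                    i + 1, rx$id[i], s))
    }
    vals <- suppressWarnings(as.numeric(vapply(kv, `[`, character(1), 2)))
    if (anyNA(vals)) {
      abort(sprintf("reactions.tsv line %d ('%s'): non-numeric coefficient in '%s'",
                    i + 1, rx$id[i], s))
    }
    stats::setNames(vals, vapply(kv, `[`, character(1), 1))
  })
  obj <- numeric()
  if ("objective" %in% names(rx)) {
    nz <- which(rx$objective != 0)
    obj <- stats::setNames(rx$objective[nz], rx$id[nz])
  }
  rxns <- tibble(id = rx$id, stoichiometry = st,
                 lower_bound = rx$lower_bound, upper_bound = rx$upper_bound,
                 gpr = if ("gpr" %in% names(rx)) ifelse(is.na(rx$gpr), "", rx$gpr) else "",
                 subsystem = if ("subsystem" %in% names(rx)) rx$subsystem else NA_character_)
  metabolic_model(mets, rxns, objective = obj, name = basename(normalizePath(path)))
}

read_model_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) abort(sprintf("SBML parse failure in %s: %s",
                                                    path, conditionMessage(e))))
  ns <- xml2::xml_ns(doc)
  sp <- xml2::xml_find_all(doc, ".//d1:listOfSpecies/d1:species", ns)
  if (length(sp) == 0) abort(sprintf("SBML model %s: no species found", path))
  mets <- tibble(
    id = xml2::xml_attr(sp, "id"),
    name = dplyr::coalesce(xml2::xml_attr(sp, "name"), xml2::xml_attr(sp, "id")),
    compartment = dplyr::coalesce(xml2::xml_attr(sp, "compartment"), "c")
  )
  boundary <- xml2::xml_attr(sp, "boundaryCondition") %in% "true"
  mets <- mets[!boundary, ]

  # fbc global parameters used for bounds
  pars <- xml2::xml_find_all(doc, ".//d1:listOfParameters/d1:parameter", ns)
  parval <- stats::setNames(as.numeric(xml2::xml_attr(pars, "value")),
                            xml2::xml_attr(pars, "id"))
  rx_nodes <- xml2::xml_find_all(doc, ".//d1:listOfReactions/d1:reaction", ns)
  obj_nodes <- xml2::xml_find_all(
    doc, ".//*[local-name()='listOfFluxObjectives']/*[local-name()='fluxObjective']")
  obj <- stats::setNames(as.numeric(xml2::xml_attr(obj_nodes, "coefficient")),
                         xml2::xml_attr(obj_nodes, "reaction"))
  rxns <- dplyr::bind_rows(lapply(rx_nodes, function(nd) {
    id <- xml2::xml_attr(nd, "id")
    spref <- function(which) {
      refs <- xml2::xml_find_all(nd, sprintf("./d1:%s/d1:speciesReference", which), ns)
      stats::setNames(
        as.numeric(dplyr::coalesce(xml2::xml_attr(refs, "stoichiometry"), "1")),
        xml2::xml_attr(refs, "species"))
    }
    sub <- spref("listOfReactants"); prod <- spref("listOfProducts")
    st <- c(-sub, prod)
    st <- st[names(st) %in% mets$id]
    st <- tapply(st, names(st), sum)
    lbp <- xml2::xml_attr(nd, "lowerFluxBound"); ubp <- xml2::xml_attr(nd, "upperFluxBound")
    rev <- xml2::xml_attr(nd, "reversible") %in% "true"
    lb <- if (!is.na(lbp) && lbp %in% names(parval)) parval[[lbp]] else if (rev) -1000 else 0
    ub <- if (!is.na(ubp) && ubp %in% names(parval)) parval[[ubp]] else 1000
    gpa <- xml2::xml_find_first(nd, ".//*[local-name()='geneProductAssociation']")
    gpr <- if (inherits(gpa, "xml_missing")) "" else sbml_gpa_to_rule(gpa)
    tibble(id = id, stoichiometry = list(stats::setNames(as.numeric(st), names(st))),
           lower_bound = lb, upper_bound = ub, gpr = gpr, subsystem = NA_character_)
  }))
  mdl <- xml2::xml_find_first(doc, ".//d1:model", ns)
  name <- xml2::xml_attr(mdl, "id")
  metabolic_model(mets, rxns, objective = obj[names(obj) %in% rxns$id],
                  name = if (is.na(name)) basename(path) else name)
}

sbml_gpa_to_rule <- function(node) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") {
    g <- xml2::xml_attr(node, "geneProduct")
    return(if (is.na(g)) "" else g)
  }
  kids <- xml2::xml_children(node)
  sub <- vapply(kids, sbml_gpa_to_rule, character(1))
  sub <- sub[nzchar(sub)]
  if (nm == "and") paste0("(", paste(sub, collapse = " and "), ")")
  else if (nm == "or") paste0("(", paste(sub, collapse = " or "), ")")
  else if (length(sub) > 0) sub[[1]] else ""
}
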