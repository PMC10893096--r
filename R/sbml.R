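# Thin SBML Level 3 + FBC adapter. Real model collections ship as SBML;
# the JSON dialect remains the canonical desk-scale format.

read_sbml_model <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("malformed SBML in '", path, "': ",
                                           conditionMessage(e)))
  model <- xml2::xml_find_first(doc, "//*[local-name()='model']")
  if (is.na(xml2::xml_name(model))) stop("SBML file has no <model> element")
  model_id <- xml2::xml_attr(model, "id")
  if (is.na(model_id)) model_id <- basename(path)

  # parameters hold the flux bound values fbc points at
  pars <- xml2::xml_find_all(doc, "//*[local-name()='parameter']")
  par_val <- setNames(as.numeric(xml2::xml_attr(pars, "value")),
                      xml2::xml_attr(pars, "id"))

  sp <- xml2::xml_find_all(doc, "//*[local-name()='species']")
  if (length(sp) == 0) stop("SBML file declares no species")
  mets <- data.frame(
    id = xml2::xml_attr(sp, "id"),
    name = ifelse(is.na(xml2::xml_attr(sp, "name")),
                  xml2::xml_attr(sp, "id"), xml2::xml_attr(sp, "name")),
    compartment = xml2::xml_attr(sp, "compartment"))
  boundary <- xml2::xml_attr(sp, "boundaryCondition") %in% "true"
  keep <- !boundary
  bound_mets <- mets$id[boundary]
  mets <- mets[keep, , drop = FALSE]

  rx_nodes <- xml2::xml_find_all(doc, "//*[local-name()='reaction']")
  if (length(rx_nodes) == 0) stop("SBML file declares no reactions")
  big <- 1e6  # stand-in for unbounded fluxes
  fetch_bound <- function(node, attr, default) {
    ref <- xml2::xml_attr(node, attr)
    if (is.na(ref)) return(default)
    v <- par_val[[ref]]
    if (is.null(v) || is.na(v)) {
      stop("flux bound parameter '", ref, "' missing for reaction '",
           xml2::xml_attr(node, "id"), "'")
    }
    max(min(v, big), -big)
  }
  rxns <- lapply(rx_nodes, function(node) {
    rid <- xml2::xml_attr(node, "id")
    if (is.na(rid)) stop("reaction without id in '", path, "'")
    sref <- function(side, sign) {
      refs <- xml2::xml_find_all(
        node, sprintf(".//*[local-name()='%s']/*[local-name()='speciesReference']", side))
      if (length(refs) == 0) return(numeric(0))
      coef <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
      coef[is.na(coef)] <- 1
      setNames(sign * coef, xml2::xml_attr(refs, "species"))
    }
    st <- c(sref("listOfReactants", -1), sref("listOfProducts", +1))
    st <- st[!(names(st) %in% bound_mets)]  # boundary species are the outside
    st <- tapply(st, names(st), sum)
    rev <- identical(xml2::xml_attr(node, "reversible"), "true")
    lb <- fetch_bound(node, "lowerFluxBound", if (rev) -big else 0)
    ub <- fetch_bound(node, "upperFluxBound", big)
    list(id = rid, stoich = setNames(as.numeric(st), names(st)), lb = lb, ub = ub)
  })

  fo <- xml2::xml_find_first(doc, "//*[local-name()='fluxObjective']")
  if (is.na(xml2::xml_name(fo))) {
    stop("SBML file declares no flux objective (fbc:listOfObjectives)")
  }
  objective <- xml2::xml_attr(fo, "reaction")
  metabolic_model(model_id, mets, rxns, objective)
}
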