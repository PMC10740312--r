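# SBML Level-3 FBC reader/writer built on xml2.
#
# Covers the subset a constraint-based model needs: species (with chemical
# formulas), reactions with stoichiometry/reversibility, flux bounds through
# fbc parameters, gene-product associations, the active fbc objective, and
# COBRA-style <notes> carrying SUBSYSTEM / GENE_ASSOCIATION (the Level-2
# dialect fallback).

sbml_attr <- function(node, name) {
  v <- xml2::xml_attr(node, paste0("fbc:", name))
  if (is.na(v)) v <- xml2::xml_attr(node, name)
  v
}

# namespace-agnostic xpath: matches by local element name at any prefix
ln_path <- function(..., anywhere = TRUE) {
  parts <- vapply(c(...), function(p)
    sprintf("*[local-name()='%s']", p), character(1))
  paste0(if (anywhere) ".//" else "./", paste(parts, collapse = "/"))
}

#' Read an SBML model
#'
#' Parses SBML Level 3 with the FBC package (flux bounds, gene-product
#' associations, active objective) or Level 2 COBRA-dialect files where GPR
#' and subsystem live in `<notes>` lines (`GENE_ASSOCIATION: ...`,
#' `SUBSYSTEM: ...`). GPR strings are normalized to lowercase `and`/`or`.
#'
#' @param path SBML file path.
#' @param objective optional reaction id overriding (or supplying, for files
#'   without an FBC objective) the biomass reaction.
#' @return A [metabolic_model()].
#' @export
read_sbml <- function(path, objective = NULL) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    stop("malformed SBML in '", path, "': ", conditionMessage(e))
  })
  model <- xml2::xml_find_first(doc, ln_path("model"))
  if (is.na(xml2::xml_name(model))) stop("malformed SBML: no <model> element")

  # flux-bound parameters
  pars <- xml2::xml_find_all(doc, ln_path("listOfParameters", "parameter"))
  par_val <- stats::setNames(as.numeric(xml2::xml_attr(pars, "value")),
                             xml2::xml_attr(pars, "id"))

  sp <- xml2::xml_find_all(doc, ln_path("listOfSpecies", "species"))
  sp_id <- xml2::xml_attr(sp, "id")
  boundary <- xml2::xml_attr(sp, "boundaryCondition") %in% "true"
  formulas <- vapply(sp, function(s) {
    f <- sbml_attr(s, "chemicalFormula")
    if (is.na(f)) "" else f
  }, character(1))
  names(formulas) <- sp_id
  keep_sp <- sp_id[!boundary]

  gp <- xml2::xml_find_all(doc, ln_path("listOfGeneProducts", "geneProduct"))
  gp_label <- stats::setNames(
    ifelse(is.na(sbml_attr_vec(gp, "label")), sbml_attr_vec(gp, "id"),
           sbml_attr_vec(gp, "label")),
    sbml_attr_vec(gp, "id"))

  rx <- xml2::xml_find_all(doc, ln_path("listOfReactions", "reaction"))
  if (!length(rx)) stop("malformed SBML: model has no reactions")
  rid <- xml2::xml_attr(rx, "id")
  n <- length(rid)
  lower <- numeric(n); upper <- numeric(n)
  gprs <- character(n); subs <- character(n)
  stoich <- vector("list", n)

  for (j in seq_len(n)) {
    r <- rx[[j]]
    rev <- xml2::xml_attr(r, "reversible") %in% c("true", NA)
    lb_ref <- sbml_attr(r, "lowerFluxBound")
    ub_ref <- sbml_attr(r, "upperFluxBound")
    lower[j] <- if (!is.na(lb_ref) && lb_ref %in% names(par_val)) {
      par_val[[lb_ref]]
    } else if (rev) -1000 else 0
    upper[j] <- if (!is.na(ub_ref) && ub_ref %in% names(par_val)) {
      par_val[[ub_ref]]
    } else 1000

    co <- numeric(0)
    for (side in c("listOfReactants", "listOfProducts")) {
      sgn <- if (side == "listOfReactants") -1 else 1
      refs <- xml2::xml_find_all(r, ln_path(side, "speciesReference", anywhere = FALSE))
      for (ref in refs) {
        id <- xml2::xml_attr(ref, "species")
        if (!id %in% keep_sp) next
        st <- xml2::xml_attr(ref, "stoichiometry")
        st <- if (is.na(st)) 1 else as.numeric(st)
        co[id] <- (if (id %in% names(co)) co[id] else 0) + sgn * st
      }
    }
    stoich[[j]] <- co

    assoc <- xml2::xml_find_first(r, ln_path("geneProductAssociation", anywhere = FALSE))
    if (!is.na(xml2::xml_name(assoc))) {
      gprs[j] <- gpa_to_string(xml2::xml_children(assoc)[[1]], gp_label)
    }
    notes <- xml2::xml_text(xml2::xml_find_first(r, ln_path("notes", anywhere = FALSE)))
    if (!is.na(notes)) {
      ga <- regmatches(notes, regexec("GENE_ASSOCIATION:\\s*([^\n<]*)", notes))[[1]]
      if (length(ga) == 2 && !nzchar(gprs[j])) gprs[j] <- trimws(ga[2])
      ss <- regmatches(notes, regexec("SUBSYSTEM:\\s*([^\n<]*)", notes))[[1]]
      if (length(ss) == 2) subs[j] <- trimws(ss[2])
    }
  }

  mets <- sort_c(unique(unlist(lapply(stoich, names))))
  S <- matrix(0, length(mets), n, dimnames = list(mets, rid))
  for (j in seq_len(n)) {
    if (length(stoich[[j]])) S[names(stoich[[j]]), j] <- stoich[[j]]
  }

  if (is.null(objective)) {
    fo <- xml2::xml_find_first(doc, ln_path("fluxObjective"))
    if (!is.na(xml2::xml_name(fo))) objective <- sbml_attr(fo, "reaction")
  }
  if (is.null(objective) || is.na(objective)) {
    stop("SBML file declares no objective; pass `objective=` to name the ",
         "biomass reaction")
  }
  metabolic_model(S, lower, upper, gprs, subs, objective,
                  metabolite_formulas = formulas[nzchar(formulas)])
}

sbml_attr_vec <- function(nodes, name) {
  vapply(nodes, sbml_attr, character(1), name = name)
}

gpa_to_string <- function(node, labels) {
  nm <- sub("^.*:", "", xml2::xml_name(node))
  if (nm == "geneProductRef") {
    id <- sbml_attr(node, "geneProduct")
    return(if (id %in% names(labels)) labels[[id]] else id)
  }
  kids <- vapply(xml2::xml_children(node), gpa_to_string, character(1),
                 labels = labels)
  paste0("(", paste(kids, collapse = paste0(" ", nm, " ")), ")")
}

#' Write a model as SBML Level 3 + FBC
#'
#' Inverse of [read_sbml()] for the model subset this package uses; GPR
#' strings are re-emitted as `fbc:geneProductAssociation` trees and subsystem
#' labels as COBRA-style notes.
#'
#' @param model a [metabolic_model()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sbml <- function(model, path) {
  esc <- function(x) gsub("&", "&amp;", gsub("<", "&lt;", x))
  bnds <- sort(unique(c(model$reactions$lower, model$reactions$upper)))
  fmt1 <- function(v) format(v, digits = 12, trim = TRUE)
  pid <- stats::setNames(paste0("bnd_", seq_along(bnds)),
                         vapply(bnds, fmt1, character(1)))
  pref <- function(v) pid[[fmt1(v)]]
  genes <- sort_c(unique(unlist(lapply(model$reactions$gpr, function(g) {
    if (nzchar(g)) gpr_genes(parse_gpr(g)) else character(0)
  }))))
  L <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    paste0('<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
           'xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" ',
           'level="3" version="1" fbc:required="false">'),
    '  <model id="model" fbc:strict="true">',
    '    <listOfCompartments><compartment id="c" constant="true"/></listOfCompartments>',
    '    <listOfParameters>',
    vapply(seq_along(bnds), function(i) sprintf(
      '      <parameter id="%s" value="%s" constant="true"/>',
      pid[[i]], format(bnds[i], digits = 12)), character(1)),
    '    </listOfParameters>',
    '    <listOfSpecies>')
  for (i in seq_len(nrow(model$metabolites))) {
    f <- model$metabolites$formula[i]
    L <- c(L, sprintf(
      '      <species id="%s" compartment="c" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"%s/>',
      esc(model$metabolites$id[i]),
      if (!is.na(f) && nzchar(f)) sprintf(' fbc:chemicalFormula="%s"', esc(f)) else ""))
  }
  L <- c(L, '    </listOfSpecies>', '    <fbc:listOfGeneProducts>',
         vapply(genes, function(g) sprintf(
           '      <fbc:geneProduct fbc:id="G_%s" fbc:label="%s"/>',
           esc(g), esc(g)), character(1)),
         '    </fbc:listOfGeneProducts>', '    <listOfReactions>')
  for (j in seq_len(nrow(model$reactions))) {
    r <- model$reactions[j, ]
    col <- model$S[, j]
    rcts <- which(col < 0); prds <- which(col > 0)
    L <- c(L, sprintf(
      '      <reaction id="%s" reversible="%s" fast="false" fbc:lowerFluxBound="%s" fbc:upperFluxBound="%s">',
      esc(r$id), tolower(r$lower < 0), pref(r$lower), pref(r$upper)))
    if (nzchar(r$subsystem)) {
      L <- c(L, sprintf(
        '        <notes><body xmlns="http://www.w3.org/1999/xhtml"><p>SUBSYSTEM: %s</p></body></notes>',
        esc(r$subsystem)))
    }
    for (side in list(c("listOfReactants", "rcts"), c("listOfProducts", "prds"))) {
      idx <- if (side[2] == "rcts") rcts else prds
      if (!length(idx)) next
      L <- c(L, sprintf('        <%s>', side[1]),
             vapply(idx, function(i) sprintf(
               '          <speciesReference species="%s" stoichiometry="%s" constant="true"/>',
               esc(rownames(model$S)[i]), format(abs(col[i]), digits = 12)),
               character(1)),
             sprintf('        </%s>', side[1]))
    }
    if (nzchar(r$gpr)) {
      L <- c(L, '        <fbc:geneProductAssociation>',
             paste0("          ", gpr_to_fbc(parse_gpr(r$gpr))),
             '        </fbc:geneProductAssociation>')
    }
    L <- c(L, '      </reaction>')
  }
  L <- c(L, '    </listOfReactions>',
         sprintf('    <fbc:listOfObjectives fbc:activeObjective="obj"><fbc:objective fbc:id="obj" fbc:type="maximize"><fbc:listOfFluxObjectives><fbc:fluxObjective fbc:reaction="%s" fbc:coefficient="1"/></fbc:listOfFluxObjectives></fbc:objective></fbc:listOfObjectives>',
                 esc(model$objective)),
         '  </model>', '</sbml>')
  writeLines(unlist(L), path)
  invisible(path)
}

gpr_to_fbc <- function(tree) {
  if (!is.null(tree$gene)) {
    return(sprintf('<fbc:geneProductRef fbc:geneProduct="G_%s"/>', tree$gene))
  }
  kids <- vapply(tree$args, gpr_to_fbc, character(1))
  sprintf("<fbc:%s>%s</fbc:%s>", tree$op, paste(kids, collapse = ""), tree$op)
}
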