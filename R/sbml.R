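#' SBML Level 3 export and import
#'
#' Networks export to SBML L3 core with fixed species as boundary species,
#' kinetic parameters as global parameters (id `<reaction>_<name>`), and
#' every rate law as an explicit MathML kinetic law generated from the same
#' formula templates the evaluator implements. Import parses the MathML back
#' into R expressions, yielding an equivalent network (same steady state).
#'
#' @name sbml
#' @keywords internal
NULL

# infix formula templates per mechanism; tokens are role letters and
# parameter names, substituted longest-first. These are the authoritative
# textual forms of the implemented rate laws (also used by the SBML export).
.mech_formula <- list(
  ter_bi = "(Vmaxf/(Ka*Kb*Kc))*(A*B*C-P*Q/Keq)/(1+A/Ka+A*B/(Ka*Kb)+A*B*C/(Ka*Kb*Kc)+P*Q/(Kp*Kq)+Q/Kq)",
  random_bi_bi = "(Vmaxf/(Ka*Kb))*(A*B-P*Q/Keq)/(1+A/Ka+B/Kb+A*B/(Ka*Kb)+P/Kp+Q/Kq+P*Q/(Kp*Kq)+A*Q/(Ka*Kq)+P*B/(Kp*Kb))",
  uni_uni = "(Vmaxf/Ka)*(A-P/Keq)/(1+A/Ka+P/Kp)",
  mwc_idh = "Vmaxf*((A/(Ka*(1+Q/Ki_NADH_vs_NAD)))/(1+A/(Ka*(1+Q/Ki_NADH_vs_NAD)))*((B/Kb)*(1+B/Kb)^(n-1))/(L*(1+Q/Ki_NADH_vs_Iso)^n+(1+B/Kb)^n)-(P*Q/(Kp*Kq*Keq))/(1+P/Kp+Q/Kq+P*Q/(Kp*Kq)))",
  bi_bi_inhib = "(Vmaxf/(Ka*Kb))*(A*B-P*Q/Keq)/(1+A/Ka+A*GSH/(Ka*Ki_GSH)+A*B/(Ka*Kb)+Q*B/(Kq*Kb)+Q*P/(Kq*Kp)+Q/Kq+NAD/Ki_NAD)",
  ter_ter = "(Vmaxf/(Ka*Kb*Kc))*(A*B*C-P*Q*R/Keq)/(1+A/Ka+A*B/(Ka*Kb)+A*B*C/(Ka*Kb*Kc)+P*Q*R/(Kp*Kq*Kr)+Q*R/(Kq*Kr)+R/Kr)",
  bi_bi = "(Vmaxf/(Ka*Kb))*(A*B-P*Q/Keq)/(1+A/Ka+A*B/(Ka*Kb)+P*Q/(Kp*Kq)+Q/Kq)",
  uni_uni_2V = "(Vmaxf*A/Ka-Vmaxr*P/Kp)/(1+A/Ka+P/Kp)",
  bi_bi_2V = "(Vmaxf*A*B/(Ka*Kb)-Vmaxr*P*Q/(Kp*Kq))/(1+A/Ka+A*B/(Ka*Kb)+P*Q/(Kp*Kq)+Q/Kq)",
  gdh_mwc = "Vmaxf*(A*B/(Ka*Kb))/(1+A/Ka+A*B/(Ka*Kb))-Vmaxr*((P*Q/(Kp*Kq))/(1+P/Kp+P*Q/(Kp*Kq)))*((R/Kr)*(1+R/Kr)^(n-1)/(L*(1+GTP/Ki_GTP)^n/(1+ADP/Ka_ADP)+(1+R/Kr)^n))",
  gr_bi_ter = "(Vmaxf/(Ka*Kb))*(A*B-P*Q*R/Keq)/(1+A/Ka+A*B/(Ka*Kb)+P*Q*R/(Kp*Kq*Kr)+Q*R/(Kq*Kr)+Q/Kq+R/Kr)",
  constant_flux = "Vc*S/(S+1e-06)"
)

# substitute role species ids and reaction-scoped parameter ids into a
# mechanism formula; returns an R expression string
.kc_formula_string <- function(r) {
  tmpl <- .mech_formula[[r$mechanism]]
  if (is.null(tmpl)) stop("no formula template for mechanism ", r$mechanism)
  subs <- c(
    stats::setNames(as.list(paste0(r$id, "_", names(r$params))), names(r$params)),
    stats::setNames(as.list(unname(r$roles)), names(r$roles))
  )
  for (tok in names(subs)[order(-nchar(names(subs)))]) {
    tmpl <- gsub(paste0("\\b", tok, "\\b"), subs[[tok]], tmpl, perl = TRUE)
  }
  paste0(r$id, "_activity*(", tmpl, ")")
}

# --- R expression <-> MathML -------------------------------------------------

.mathml_op <- c(`+` = "plus", `-` = "minus", `*` = "times", `/` = "divide",
                `^` = "power")

.expr_to_mathml <- function(e) {
  if (is.numeric(e)) {
    if (e == floor(e) && abs(e) < 1e15)
      return(sprintf("<cn type=\"integer\">%d</cn>", as.integer(e)))
    return(sprintf("<cn type=\"e-notation\">%s<sep/>%d</cn>",
                   format(e / 10^floor(log10(abs(e))), digits = 17),
                   as.integer(floor(log10(abs(e))))))
  }
  if (is.name(e)) return(sprintf("<ci> %s </ci>", as.character(e)))
  if (is.call(e)) {
    op <- as.character(e[[1]])
    if (op == "(") return(.expr_to_mathml(e[[2]]))
    if (!op %in% names(.mathml_op)) stop("unsupported operator in MathML export: ", op)
    args <- lapply(as.list(e)[-1], .expr_to_mathml)
    return(paste0("<apply><", .mathml_op[[op]], "/>",
                  paste0(unlist(args), collapse = ""), "</apply>"))
  }
  stop("unsupported expression node for MathML export")
}

.mathml_to_expr <- function(node) {
  nm <- xml2::xml_name(node)
  if (nm == "math") return(.mathml_to_expr(xml2::xml_child(node)))
  if (nm == "ci") return(as.name(trimws(xml2::xml_text(node))))
  if (nm == "cn") {
    type <- xml2::xml_attr(node, "type")
    if (!is.na(type) && type == "e-notation") {
      kids <- xml2::xml_contents(node)
      txt <- trimws(xml2::xml_text(kids[1]))
      expv <- trimws(xml2::xml_text(kids[length(kids)]))
      return(as.numeric(txt) * 10^as.numeric(expv))
    }
    return(as.numeric(trimws(xml2::xml_text(node))))
  }
  if (nm == "apply") {
    kids <- xml2::xml_children(node)
    op <- xml2::xml_name(kids[[1]])
    rop <- names(.mathml_op)[match(op, .mathml_op)]
    if (is.na(rop)) stop("unsupported MathML operator: ", op)
    args <- lapply(kids[-1], .mathml_to_expr)
    if (length(args) == 1 && rop == "-") return(call("-", args[[1]]))
    e <- args[[1]]
    for (a in args[-1]) e <- call(rop, e, a)
    return(e)
  }
  stop("unsupported MathML node: ", nm)
}

#' Export a network as an SBML Level 3 document
#'
#' @param net `kc_network`
#' @param path output .xml file
#' @return path, invisibly
#' @export
export_sbml <- function(net, path) {
  esc <- function(x) gsub("&", "&amp;", x)
  lines <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    "<sbml xmlns=\"http://www.sbml.org/sbml/level3/version2/core\" level=\"3\" version=\"2\">",
    sprintf("  <model id=\"KC_%s\" name=\"Krebs cycle kinetic model (%s)\">",
            esc(net$tissue), esc(net$tissue)),
    "    <listOfCompartments>",
    "      <compartment id=\"matrix\" size=\"1\" constant=\"true\"/>",
    "    </listOfCompartments>",
    "    <listOfSpecies>")
  for (i in seq_len(nrow(net$species))) {
    s <- net$species[i, ]
    lines <- c(lines, sprintf(
      paste0("      <species id=\"%s\" compartment=\"matrix\" ",
             "initialConcentration=\"%s\" boundaryCondition=\"%s\" ",
             "hasOnlySubstanceUnits=\"false\" constant=\"false\"/>"),
      s$id, format(s$conc, digits = 17),
      if (s$role == "fixed") "true" else "false"))
  }
  lines <- c(lines, "    </listOfSpecies>", "    <listOfParameters>")
  for (r in net$reactions) {
    for (nm in names(r$params))
      lines <- c(lines, sprintf(
        "      <parameter id=\"%s_%s\" value=\"%s\" constant=\"true\"/>",
        r$id, nm, format(r$params[[nm]], digits = 17)))
    lines <- c(lines, sprintf(
      "      <parameter id=\"%s_activity\" value=\"%s\" constant=\"true\"/>",
      r$id, format(r$activity, digits = 17)))
  }
  lines <- c(lines, "    </listOfParameters>", "    <listOfReactions>")
  for (r in net$reactions) {
    lines <- c(lines, sprintf(
      "      <reaction id=\"%s\" reversible=\"true\">", r$id))
    sub <- r$stoich[r$stoich < 0]; prod <- r$stoich[r$stoich > 0]
    if (length(sub)) {
      lines <- c(lines, "        <listOfReactants>")
      for (s in names(sub))
        lines <- c(lines, sprintf(
          "          <speciesReference species=\"%s\" stoichiometry=\"%s\" constant=\"true\"/>",
          s, format(-sub[[s]])))
      lines <- c(lines, "        </listOfReactants>")
    }
    if (length(prod)) {
      lines <- c(lines, "        <listOfProducts>")
      for (s in names(prod))
        lines <- c(lines, sprintf(
          "          <speciesReference species=\"%s\" stoichiometry=\"%s\" constant=\"true\"/>",
          s, format(prod[[s]])))
      lines <- c(lines, "        </listOfProducts>")
    }
    mods <- setdiff(unname(r$roles), names(r$stoich))
    if (length(mods)) {
      lines <- c(lines, "        <listOfModifiers>")
      for (s in unique(mods))
        lines <- c(lines, sprintf(
          "          <modifierSpeciesReference species=\"%s\"/>", s))
      lines <- c(lines, "        </listOfModifiers>")
    }
    ex <- str2lang(.kc_formula_string(r))
    lines <- c(lines,
      "        <kineticLaw>",
      "          <math xmlns=\"http://www.w3.org/1998/Math/MathML\">",
      paste0("            ", .expr_to_mathml(ex)),
      "          </math>",
      "        </kineticLaw>",
      "      </reaction>")
  }
  lines <- c(lines, "    </listOfReactions>", "  </model>", "</sbml>")
  writeLines(lines, path)
  # validate well-formedness
  xml2::read_xml(path)
  invisible(path)
}

#' Import an SBML Level 3 document written by [export_sbml()]
#'
#' Species, stoichiometry and global parameters are read from the SBML
#' elements; each kinetic law's MathML is parsed back into an R expression.
#' The resulting network evaluates rates from those expressions and has the
#' same steady state as the exported network.
#'
#' @param path SBML file
#' @return `kc_network` with expression-backed reactions
#' @export
import_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- c(s = "http://www.sbml.org/sbml/level3/version2/core",
          m = "http://www.w3.org/1998/Math/MathML")
  spn <- xml2::xml_find_all(doc, ".//s:species", ns)
  species <- data.frame(
    id = xml2::xml_attr(spn, "id"),
    role = ifelse(xml2::xml_attr(spn, "boundaryCondition") == "true",
                  "fixed", "variable"),
    conc = as.numeric(xml2::xml_attr(spn, "initialConcentration")),
    stringsAsFactors = FALSE)
  pn <- xml2::xml_find_all(doc, ".//s:parameter", ns)
  pars <- stats::setNames(as.numeric(xml2::xml_attr(pn, "value")),
                          xml2::xml_attr(pn, "id"))
  rn <- xml2::xml_find_all(doc, ".//s:reaction", ns)
  reactions <- lapply(rn, function(node) {
    id <- xml2::xml_attr(node, "id")
    rs <- xml2::xml_find_all(node, "./s:listOfReactants/s:speciesReference", ns)
    ps <- xml2::xml_find_all(node, "./s:listOfProducts/s:speciesReference", ns)
    st <- c(
      stats::setNames(-as.numeric(xml2::xml_attr(rs, "stoichiometry")),
                      xml2::xml_attr(rs, "species")),
      stats::setNames(as.numeric(xml2::xml_attr(ps, "stoichiometry")),
                      xml2::xml_attr(ps, "species")))
    math <- xml2::xml_find_first(node, "./s:kineticLaw/m:math", ns)
    ex <- .mathml_to_expr(math)
    vars <- all.vars(ex)
    roles <- intersect(vars, species$id)
    list(id = id, mechanism = "sbml_math", expr = ex,
         roles = stats::setNames(roles, roles), stoich = st,
         params = as.list(pars[intersect(vars, names(pars))]),
         activity = 1)
  })
  kc_network(species, reactions, moieties = list(),
             tissue = sub("^KC_", "", xml2::xml_attr(
               xml2::xml_find_first(doc, ".//s:model", ns), "id")),
             kc_flux_reaction = if ("MDH" %in% vapply(reactions, `[[`, "", "id"))
               "MDH" else NULL)
}
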