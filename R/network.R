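#' Reaction topology shared by the three tissue models
#'
#' Returns the full reaction list (id, mechanism, role bindings, signed
#' stoichiometry over variable species). Fixed species appear in role
#' bindings but never in stoichiometry. Tissue exclusions are applied by
#' [build_model()]: RLM has no ME and no Mal/2-oxo exchanger, RHM has no ALT.
#' @return list of reaction descriptors
#' @keywords internal
.kc_reaction_table <- function() {
  rxn <- function(id, mechanism, roles, stoich)
    list(id = id, mechanism = mechanism, roles = roles, stoich = stoich)
  list(
    rxn("PT", "uni_uni", c(A = "Pyr_out", P = "Pyr"), c(Pyr = 1)),
    rxn("PDH", "ter_bi", c(A = "Pyr", B = "CoA", C = "NAD", P = "AcCoA", Q = "NADH"),
        c(Pyr = -1, CoA = -1, NAD = -1, AcCoA = 1, NADH = 1)),
    rxn("CS", "random_bi_bi", c(A = "AcCoA", B = "OAA", P = "CoA", Q = "Cit"),
        c(AcCoA = -1, OAA = -1, CoA = 1, Cit = 1)),
    rxn("ACO", "uni_uni", c(A = "Cit", P = "Iso"), c(Cit = -1, Iso = 1)),
    rxn("IDH_NAD", "mwc_idh", c(A = "NAD", B = "Iso", P = "OXO", Q = "NADH"),
        c(NAD = -1, Iso = -1, OXO = 1, NADH = 1)),
    rxn("IDH_NADP", "bi_bi_inhib",
        c(A = "NADP", B = "Iso", P = "OXO", Q = "NADPH", GSH = "GSH", NAD = "NAD"),
        c(NADP = -1, Iso = -1, OXO = 1, NADPH = 1)),
    rxn("OGDH", "ter_bi", c(A = "OXO", B = "CoA", C = "NAD", P = "SCoA", Q = "NADH"),
        c(OXO = -1, CoA = -1, NAD = -1, SCoA = 1, NADH = 1)),
    rxn("SCS", "ter_ter",
        c(A = "SCoA", B = "ADP", C = "Pi", P = "ATP", Q = "CoA", R = "Suc"),
        c(SCoA = -1, CoA = 1, Suc = 1)),
    rxn("SDH", "bi_bi", c(A = "Suc", B = "CoQ", P = "QH2", Q = "Fum"),
        c(Suc = -1, Fum = 1)),
    rxn("FH", "uni_uni_2V", c(A = "Fum", P = "Mal"), c(Fum = -1, Mal = 1)),
    rxn("MDH", "bi_bi_2V", c(A = "NAD", B = "Mal", P = "OAA", Q = "NADH"),
        c(NAD = -1, Mal = -1, OAA = 1, NADH = 1)),
    rxn("AST", "bi_bi", c(A = "Asp", B = "OXO", P = "OAA", Q = "Glu"),
        c(OXO = -1, OAA = 1)),
    rxn("ALT", "bi_bi", c(A = "Ala", B = "OXO", P = "Pyr", Q = "Glu"),
        c(OXO = -1, Pyr = 1)),
    rxn("ME", "bi_bi", c(A = "NADP", B = "Mal", P = "Pyr", Q = "NADPH"),
        c(NADP = -1, Mal = -1, Pyr = 1, NADPH = 1)),
    rxn("GDH", "gdh_mwc",
        c(A = "NADP", B = "Glu", P = "OXO", Q = "NADPH", R = "NH4",
          GTP = "GTP", ADP = "ADP"),
        c(NADP = -1, OXO = 1, NADPH = 1)),
    rxn("GR", "gr_bi_ter", c(A = "NADPH", B = "GSSG", P = "NADP", Q = "GSH", R = "GSH"),
        c(NADPH = -1, GSSG = -1, NADP = 1, GSH = 2)),
    rxn("MAL_SUC", "bi_bi", c(A = "Mal_out", B = "Suc", P = "Mal", Q = "Suc_out"),
        c(Suc = -1, Mal = 1)),
    rxn("MAL_ISO", "bi_bi", c(A = "Mal_out", B = "Iso", P = "Mal", Q = "Iso_out"),
        c(Iso = -1, Mal = 1)),
    rxn("MAL_OXO", "bi_bi", c(A = "Mal_out", B = "OXO", P = "Mal", Q = "OXO_out"),
        c(OXO = -1, Mal = 1)),
    rxn("NADH_CONS", "constant_flux", c(S = "NADH"), c(NADH = -1, NAD = 1)),
    rxn("GSH_OX", "constant_flux", c(S = "GSH"), c(GSH = -2, GSSG = 1))
  )
}

# conserved cofactor moieties; the first species of each is the
# pool-balancing member used when normalizing initial states and when
# eliminating dependent species for Newton refinement
.kc_moieties <- function() list(
  NAD_pool  = c(NAD = 1, NADH = 1),
  NADP_pool = c(NADP = 1, NADPH = 1),
  GSH_pool  = c(GSH = 1, GSSG = 2),
  CoA_pool  = c(CoA = 1, AcCoA = 1, SCoA = 1)
)

.kc_tissues <- c("HepM", "RLM", "RHM")

.kc_excluded <- list(
  HepM = character(0),
  RLM  = c("ME", "MAL_OXO"),
  RHM  = "ALT"
)

#' Fold the fixed CO2 concentration into an equilibrium constant
#'
#' Decarboxylating steps (PDH, both IDH isoforms, 2OGDH) have CO2 as a fixed
#' product; its concentration is absorbed into the equilibrium constant as
#' Keq_effective = Keq_raw / \[CO2\].
#'
#' @param keq_raw equilibrium constant including CO2 (mM units)
#' @param co2 fixed CO2 concentration (mM), default 2.2
#' @return effective Keq
#' @export
fold_co2_keq <- function(keq_raw, co2 = 2.2) {
  stopifnot(keq_raw > 0, co2 > 0)
  keq_raw / co2
}

#' Load a tissue kinetic-parameter fixture
#'
#' Reads the tabular parameter file (enzyme_id, mechanism, name, value,
#' units, provenance) shipped under `inst/extdata`, layering a fitted
#' (CALIBRATED) file on top when present.
#'
#' @param tissue one of "HepM", "RLM", "RHM"
#' @param use_fitted overlay calibrated activities if a fitted fixture exists
#' @return data.frame of parameter rows
#' @export
kc_params <- function(tissue, use_fitted = TRUE) {
  tissue <- match.arg(tissue, .kc_tissues)
  path <- system.file("extdata", paste0("params_", tissue, ".csv"),
                      package = "krebsmca")
  if (path == "") stop("parameter fixture for ", tissue, " not found")
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (use_fitted) {
    fp <- system.file("extdata", paste0("params_fitted_", tissue, ".csv"),
                      package = "krebsmca")
    if (fp != "") {
      fit <- utils::read.csv(fp, stringsAsFactors = FALSE)
      for (i in seq_len(nrow(fit))) {
        j <- which(tab$enzyme_id == fit$enzyme_id[i] & tab$name == fit$name[i])
        if (length(j) == 1) {
          tab$value[j] <- fit$value[i]
          tab$provenance[j] <- "CALIBRATED"
        } else {
          fit_row <- fit[i, ]
          tab <- rbind(tab, fit_row)
        }
      }
    }
  }
  tab
}

#' Build a tissue Krebs-cycle reaction network
#'
#' Assembles the species list (variable + fixed boundary species), reactions
#' with rate-law bindings, activity scalings, conserved moiety definitions
#' and initial state from the shipped fixtures. CO2 (fixed, 2.2 mM) is
#' folded into the Keq of the decarboxylating steps. Initial cofactor
#' concentrations are normalized so every conserved pool matches its
#' configured total exactly.
#'
#' @param tissue one of "HepM", "RLM", "RHM"
#' @param overrides named list of parameter overrides, keys "REACTION.param"
#'   (e.g. `list("PDH.Vmaxf" = 26)`) or "fixed.SPECIES" for boundary
#'   concentrations
#' @param use_fitted overlay calibrated activities (default TRUE)
#' @return object of class `kc_network`
#' @export
build_model <- function(tissue, overrides = list(), use_fitted = TRUE) {
  tissue <- match.arg(tissue, .kc_tissues)
  tab <- kc_params(tissue, use_fitted = use_fitted)

  sp <- system.file("extdata", paste0("state_", tissue, ".json"),
                    package = "krebsmca")
  if (sp == "") stop("state fixture for ", tissue, " not found")
  st <- jsonlite::read_json(sp, simplifyVector = TRUE)
  fixed <- unlist(st$fixed)
  x0 <- unlist(st$initial)
  totals <- unlist(st$moiety_totals)

  # apply fixed-species overrides before folding CO2
  for (key in names(overrides)) {
    if (startsWith(key, "fixed.")) {
      id <- sub("^fixed\\.", "", key)
      if (!id %in% names(fixed)) stop("override references unknown fixed species: ", id)
      fixed[[id]] <- overrides[[key]]
    }
  }

  keep <- setdiff(vapply(.kc_reaction_table(), `[[`, "", "id"),
                  .kc_excluded[[tissue]])
  rxns <- Filter(function(r) r$id %in% keep, .kc_reaction_table())

  reactions <- lapply(rxns, function(r) {
    rows <- tab[tab$enzyme_id == r$id, ]
    if (!nrow(rows))
      stop("load error: no parameters for reaction ", r$id, " in ", tissue,
           " fixture (provenance slot PAPER-Table1/SM1/FREE)")
    p <- as.list(stats::setNames(rows$value, rows$name))
    prov <- stats::setNames(rows$provenance, rows$name)
    activity <- if (!is.null(p$activity)) p$activity else 1
    p$activity <- NULL
    co2_folded <- isTRUE(p$co2_folded == 1)
    p$co2_folded <- NULL
    # parameter overrides
    for (key in names(overrides)) {
      if (startsWith(key, paste0(r$id, "."))) {
        nm <- sub(paste0("^", r$id, "\\."), "", key)
        if (nm == "activity") {
          activity <- overrides[[key]]
        } else {
          if (!nm %in% names(p) && !nm %in% .mech_required[[r$mechanism]])
            stop("override references unknown parameter ", key)
          p[[nm]] <- overrides[[key]]
        }
      }
    }
    if (co2_folded) p$Keq <- fold_co2_keq(p$Keq, fixed[["CO2"]])
    validate_params(p, r$mechanism, r$id)
    if (activity <= 0) stop("configuration error: activity of ", r$id, " must be > 0")
    list(id = r$id, mechanism = r$mechanism, roles = r$roles,
         stoich = r$stoich, params = p, provenance = prov,
         activity = activity, co2_folded = co2_folded)
  })
  names(reactions) <- vapply(reactions, `[[`, "", "id")

  var_ids <- c("Pyr", "AcCoA", "CoA", "Cit", "Iso", "OXO", "SCoA", "Suc",
               "Fum", "Mal", "OAA", "NAD", "NADH", "NADP", "NADPH", "GSH", "GSSG")
  moieties <- .kc_moieties()

  # balance the pools: the first (balancing) member absorbs the residual
  x <- stats::setNames(numeric(length(var_ids)), var_ids)
  x[names(x0)] <- x0
  for (m in names(moieties)) {
    coef <- moieties[[m]]
    bal <- names(coef)[1]
    rest <- sum(coef[-1] * x[names(coef)[-1]])
    val <- (totals[[m]] - rest) / coef[[bal]]
    if (val <= 0) stop("initial state incompatible with moiety total ", m)
    x[bal] <- val
  }

  net <- structure(list(
    tissue = tissue,
    species = data.frame(
      id = c(var_ids, names(fixed)),
      role = c(rep("variable", length(var_ids)), rep("fixed", length(fixed))),
      conc = c(unname(x), unname(fixed)),
      stringsAsFactors = FALSE),
    reactions = reactions,
    moieties = lapply(names(moieties), function(m)
      list(id = m, coef = moieties[[m]], total = unname(totals[[m]]))),
    kc_flux_reaction = "MDH"
  ), class = "kc_network")
  names(net$moieties) <- names(moieties)
  kc_compile(net)
}

#' Construct a network from explicit pieces (used for toy models and import)
#'
#' @param species data.frame with columns id, role ("variable"/"fixed"), conc
#' @param reactions list of reactions, each a list(id, mechanism, roles,
#'   stoich, params, activity)
#' @param moieties optional list of list(id, coef, total)
#' @param tissue label (default "custom")
#' @param kc_flux_reaction reaction whose flux is reported as the pathway flux
#' @return `kc_network`
#' @export
kc_network <- function(species, reactions, moieties = list(),
                       tissue = "custom", kc_flux_reaction = NULL) {
  for (r in reactions)
    if (r$mechanism != "sbml_math") validate_params(r$params, r$mechanism, r$id)
  names(reactions) <- vapply(reactions, `[[`, "", "id")
  reactions <- lapply(reactions, function(r) {
    if (is.null(r$activity)) r$activity <- 1
    r
  })
  net <- structure(list(tissue = tissue, species = species,
                        reactions = reactions, moieties = moieties,
                        kc_flux_reaction = kc_flux_reaction),
                   class = "kc_network")
  kc_compile(net)
}

# precompute index structures for fast evaluation
kc_compile <- function(net) {
  sp <- net$species
  all_ids <- sp$id
  var_ids <- sp$id[sp$role == "variable"]
  net$var_ids <- var_ids
  net$fixed_conc <- stats::setNames(sp$conc[sp$role == "fixed"],
                                    sp$id[sp$role == "fixed"])
  net$x0 <- stats::setNames(sp$conc[sp$role == "variable"], var_ids)
  # stoichiometric matrix: variable species x reactions
  S <- matrix(0, length(var_ids), length(net$reactions),
              dimnames = list(var_ids, names(net$reactions)))
  for (j in seq_along(net$reactions)) {
    st <- net$reactions[[j]]$stoich
    bad <- setdiff(names(st), var_ids)
    if (length(bad)) stop("stoichiometry of ", net$reactions[[j]]$id,
                          " references non-variable species: ",
                          paste(bad, collapse = ", "))
    S[names(st), j] <- st
  }
  net$S <- S
  # role index lookups into the full concentration vector c(x, fixed)
  full_ids <- c(var_ids, names(net$fixed_conc))
  net$rxn_role_idx <- lapply(net$reactions, function(r) {
    idx <- match(r$roles, full_ids)
    if (anyNA(idx)) stop("reaction ", r$id, " binds unknown species: ",
                         paste(r$roles[is.na(idx)], collapse = ", "))
    stats::setNames(idx, names(r$roles))
  })
  # pre-built evaluation environments for expression-backed (SBML) reactions
  net$rxn_env <- lapply(net$reactions, function(r) {
    if (r$mechanism == "sbml_math") list2env(r$params) else NULL
  })
  # compiled per-reaction evaluators: call the rate-law functions with
  # positional arguments via integer indexing into the full concentration
  # vector (hot path for the solvers)
  net$rxn_fun <- lapply(seq_along(net$reactions), function(j) {
    r <- net$reactions[[j]]
    if (r$mechanism == "sbml_math") {
      env <- net$rxn_env[[j]]
      idx <- net$rxn_role_idx[[j]]
      nms <- names(r$roles)
      expr <- r$expr
      return(function(full) {
        for (k in seq_along(idx)) assign(nms[k], full[[idx[k]]], envir = env)
        eval(expr, env)
      })
    }
    f <- switch(r$mechanism,
      ter_bi = rate_ter_bi, random_bi_bi = rate_random_bi_bi,
      uni_uni = rate_uni_uni, mwc_idh = rate_mwc_idh_nad,
      bi_bi_inhib = rate_idh_nadp, ter_ter = rate_ter_ter,
      bi_bi = rate_bi_bi, uni_uni_2V = rate_uni_uni_2V,
      bi_bi_2V = rate_bi_bi_2V, gdh_mwc = rate_gdh, gr_bi_ter = rate_gr,
      constant_flux = rate_constant_flux,
      stop("unknown mechanism: ", r$mechanism))
    # bind roles in the canonical mechanism order (= argument order)
    idx <- unname(net$rxn_role_idx[[j]][mechanism_roles(r$mechanism)])
    p <- r$params
    a <- r$activity
    n <- length(idx)
    switch(as.character(n),
      "1" = function(full) a * f(p, full[[idx[1]]]),
      "2" = function(full) a * f(p, full[[idx[1]]], full[[idx[2]]]),
      "4" = function(full) a * f(p, full[[idx[1]]], full[[idx[2]]],
                                 full[[idx[3]]], full[[idx[4]]]),
      "5" = function(full) a * f(p, full[[idx[1]]], full[[idx[2]]],
                                 full[[idx[3]]], full[[idx[4]]],
                                 full[[idx[5]]]),
      "6" = function(full) a * f(p, full[[idx[1]]], full[[idx[2]]],
                                 full[[idx[3]]], full[[idx[4]]],
                                 full[[idx[5]]], full[[idx[6]]]),
      "7" = function(full) a * f(p, full[[idx[1]]], full[[idx[2]]],
                                 full[[idx[3]]], full[[idx[4]]],
                                 full[[idx[5]]], full[[idx[6]]],
                                 full[[idx[7]]]),
      function(full) a * do.call(f, c(list(p), as.list(full[idx]))))
  })
  net
}

#' Evaluate all reaction rates at a state
#'
#' @param net `kc_network`
#' @param x named numeric vector of variable-species concentrations (mM);
#'   defaults to the network initial state
#' @return named numeric vector of rates, activity scalings applied
#' @export
rate_vector <- function(net, x = net$x0) {
  full <- c(x[net$var_ids], net$fixed_conc)
  fns <- net$rxn_fun
  v <- numeric(length(fns))
  for (j in seq_along(fns)) v[j] <- fns[[j]](full)
  stats::setNames(v, names(net$reactions))
}

#' Time derivatives dx/dt = S v(x)
#' @inheritParams rate_vector
#' @return named numeric vector (mM/min)
#' @export
kc_dxdt <- function(net, x = net$x0) {
  drop(net$S %*% rate_vector(net, x))
}

#' Stoichiometric matrix and conserved-moiety basis
#'
#' Rows are variable species, columns reactions. The moiety basis spans the
#' left null space of S (computed by SVD); rank(S) + number of conserved
#' moieties = number of variable species.
#'
#' @param net `kc_network`
#' @return list(S, moiety_basis, rank)
#' @export
stoichiometric_matrix <- function(net) {
  S <- net$S
  sv <- svd(S, nu = nrow(S))
  tolr <- max(dim(S)) * max(sv$d) * .Machine$double.eps
  r <- sum(sv$d > tolr)
  basis <- if (r < nrow(S)) sv$u[, (r + 1):nrow(S), drop = FALSE] else
    matrix(0, nrow(S), 0)
  rownames(basis) <- rownames(S)
  list(S = S, moiety_basis = basis, rank = r)
}

#' Conserved-moiety totals at a state
#' @param net `kc_network`
#' @param x variable-species state (default initial)
#' @return named numeric vector of pool totals (mM)
#' @export
moiety_totals <- function(net, x = net$x0) {
  vapply(net$moieties, function(m) sum(m$coef * x[names(m$coef)]), 0)
}

#' Update parameters/activities of a network (returns a recompiled copy)
#' @param net `kc_network`
#' @param values named list, keys "REACTION.param" or "REACTION.activity"
#' @return modified `kc_network`
#' @export
set_params <- function(net, values) {
  for (key in names(values)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    if (length(parts) != 2) stop("bad parameter key: ", key)
    rid <- parts[1]; nm <- parts[2]
    if (!rid %in% names(net$reactions)) stop("unknown reaction in key: ", key)
    if (nm == "activity") {
      net$reactions[[rid]]$activity <- values[[key]]
    } else {
      if (!nm %in% names(net$reactions[[rid]]$params))
        stop("unknown parameter in key: ", key)
      net$reactions[[rid]]$params[[nm]] <- values[[key]]
    }
  }
  kc_compile(net)
}

#' Get a parameter value ("REACTION.param" or "REACTION.activity")
#' @param net `kc_network`
#' @param key parameter key
#' @return numeric value
#' @export
get_param <- function(net, key) {
  parts <- strsplit(key, ".", fixed = TRUE)[[1]]
  r <- net$reactions[[parts[1]]]
  if (is.null(r)) stop("unknown reaction: ", parts[1])
  if (parts[2] == "activity") r$activity else r$params[[parts[2]]]
}

#' Provenance summary of a built network
#' @param net `kc_network`
#' @return table of provenance tag counts
#' @export
provenance_summary <- function(net) {
  tags <- unlist(lapply(net$reactions, function(r) unname(r$provenance)))
  if (is.null(tags)) return(table(character(0)))
  table(tags)
}

#' Serialize a network to a structured (JSON) config
#' @param net `kc_network`
#' @param path output file
#' @return path, invisibly
#' @export
write_network_config <- function(net, path) {
  cfg <- list(
    tissue = net$tissue,
    kc_flux_reaction = net$kc_flux_reaction,
    species = net$species,
    moieties = lapply(net$moieties, function(m)
      list(id = m$id, species = names(m$coef), coef = unname(m$coef),
           total = m$total)),
    reactions = lapply(net$reactions, function(r)
      list(id = r$id, mechanism = r$mechanism,
           roles = as.list(r$roles),
           stoich_species = names(r$stoich), stoich_coef = unname(r$stoich),
           params = r$params, activity = r$activity))
  )
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Rebuild a network from its serialized config (round-trip identity)
#' @param path JSON config written by [write_network_config()]
#' @return `kc_network`
#' @export
read_network_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  reactions <- lapply(cfg$reactions, function(r)
    list(id = r$id, mechanism = r$mechanism,
         roles = unlist(r$roles),
         stoich = stats::setNames(r$stoich_coef, r$stoich_species),
         params = lapply(r$params, as.numeric), activity = r$activity))
  moieties <- lapply(cfg$moieties, function(m)
    list(id = m$id, coef = stats::setNames(m$coef, m$species), total = m$total))
  names(moieties) <- vapply(moieties, `[[`, "", "id")
  kc_network(cfg$species, reactions, moieties, tissue = cfg$tissue,
             kc_flux_reaction = cfg$kc_flux_reaction)
}
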