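#' Tabular result writers and fixture readers
#'
#' Results are written as TSV with `#`-prefixed metadata header lines (tissue,
#' tolerances, seed, parameter provenance hash) so any published file can be
#' regenerated from its embedded configuration; numeric columns round-trip at
#' full precision.
#'
#' @name interfaces_io
#' @keywords internal
NULL

#' Write a steady-state or control-analysis result as a tabular file
#'
#' @param result `kc_steady_state`, `kc_control_analysis`, `kc_titration` or
#'   a data.frame
#' @param path output file (TSV)
#' @param meta named list of metadata recorded as header comments
#' @return path, invisibly
#' @export
write_results <- function(result, path, meta = list()) {
  if (inherits(result, "kc_steady_state")) {
    df <- rbind(
      data.frame(kind = "concentration", id = names(result$concentrations),
                 value = unname(result$concentrations)),
      data.frame(kind = "flux", id = names(result$fluxes),
                 value = unname(result$fluxes)))
    meta <- c(meta, list(kc_flux = result$kc_flux,
                         residual_norm = result$residual_norm,
                         converged = result$converged))
  } else if (inherits(result, "kc_control_analysis")) {
    df <- rbind(
      data.frame(kind = "fcc", id = names(result$fcc),
                 value = unname(result$fcc)),
      data.frame(kind = "ccc", id = names(result$ccc),
                 value = unname(result$ccc)))
    meta <- c(meta, list(ref_flux = result$ref_flux, species = result$species,
                         fcc_sum = result$fcc_sum, ccc_sum = result$ccc_sum))
  } else if (inherits(result, "kc_titration")) {
    df <- data.frame(kind = "titration", id = format(result$factors),
                     value = result$kc_flux,
                     normalized = result$normalized,
                     converged = result$converged)
    meta <- c(meta, list(reaction = result$reaction,
                         flux_ic50 = result$flux_ic50))
  } else if (is.data.frame(result)) {
    df <- result
  } else stop("unsupported result type: ", paste(class(result), collapse = "/"))
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(meta))
    writeLines(sprintf("# %s: %s", k, format(meta[[k]], digits = 17)), con)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a tabular fixture or result file
#'
#' Accepts CSV or TSV with optional `#` metadata headers; a malformed row
#' raises a parse error naming the offending line number.
#'
#' @param path input file
#' @return data.frame; metadata header lines in attribute "meta"
#' @export
read_fixture <- function(path) {
  if (!file.exists(path)) stop("fixture not found: ", path)
  lines <- readLines(path)
  metaln <- grep("^#", lines)
  meta <- sub("^#\\s*", "", lines[metaln])
  body <- if (length(metaln)) lines[-metaln] else lines
  body <- body[nzchar(body)]
  if (!length(body)) stop("empty fixture: ", path)
  sep <- if (grepl("\t", body[1])) "\t" else ","
  ncol <- length(strsplit(body[1], sep, fixed = TRUE)[[1]])
  for (i in seq_along(body)) {
    if (length(strsplit(body[i], sep, fixed = TRUE)[[1]]) != ncol)
      stop("parse error in ", path, " at line ",
           if (length(metaln)) i + length(metaln) else i,
           ": expected ", ncol, " fields")
  }
  df <- utils::read.table(text = body, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE)
  attr(df, "meta") <- meta
  df
}

#' Short provenance hash of a network's parameterization
#' @param net `kc_network`
#' @return character checksum
#' @export
provenance_hash <- function(net) {
  vals <- unlist(lapply(net$reactions, function(r)
    c(r$params, activity = r$activity)))
  txt <- paste(names(vals), format(vals, digits = 17), collapse = ";")
  # simple rolling checksum (no digest dependency)
  h <- 0
  for (ch in utf8ToInt(txt)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", h)
}
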