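#' Construct a splicing-regulatory-element motif set
#'
#' A motif set is a catalog of hexamer (6-mer) motifs of one SRE category:
#' exonic splicing enhancers (ESE), exonic splicing silencers (ESS) or
#' intronic splicing enhancers (ISE).
#'
#' @param category One of `"ESE"`, `"ESS"`, `"ISE"`.
#' @param hexamers Character vector of uppercase length-6 strings over ACGT.
#' @return An object of class `sre_motif_set`.
#' @export
motif_set <- function(category, hexamers) {
  category <- match.arg(category, c("ESE", "ESS", "ISE"))
  hexamers <- toupper(as.character(hexamers))
  bad <- !grepl("^[ACGT]{6}$", hexamers)
  if (any(bad))
    stop("invalid hexamer(s) for ", category, ": ",
         paste(utils::head(hexamers[bad], 5), collapse = ", "))
  structure(list(category = category, hexamers = unique(hexamers)),
            class = "sre_motif_set")
}

#' Read a hexamer motif list from a plain-text file
#'
#' One uppercase 6-mer per line; `#` starts a comment; blank lines ignored.
#'
#' @param path Path to the motif file.
#' @inheritParams motif_set
#' @return An `sre_motif_set`.
#' @export
read_motifs <- function(path, category) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("no motifs found in ", path)
  motif_set(category, lines)
}

#' Read the three SRE motif catalogs
#'
#' @param ese,ess,ise Paths to the ESE, ESS and ISE hexamer lists.
#' @return Named list of three `sre_motif_set` objects.
#' @export
read_motif_sets <- function(ese, ess, ise) {
  list(ESE = read_motifs(ese, "ESE"),
       ESS = read_motifs(ess, "ESS"),
       ISE = read_motifs(ise, "ISE"))
}

#' @export
print.sre_motif_set <- function(x, ...) {
  cat(sprintf("%s motif set: %d hexamers (e.g. %s)\n", x$category,
              length(x$hexamers),
              paste(utils::head(x$hexamers, 3), collapse = ", ")))
  invisible(x)
}
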