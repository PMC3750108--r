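#' Construct a metabolic network model
#'
#' A network is a set of reactions over declared metabolites, split into an
#' internal set (balanced at steady state) and an external set (sources and
#' sinks, not balanced). Reversibility is tracked per reaction; the
#' irreversible reactions carry the sign constraints of the flux cone.
#'
#' @param reaction_ids Character vector of unique reaction names, in model
#'   order (reversible block first by convention of the Metatool dialect).
#' @param stoich Numeric matrix, metabolites x reactions, with dimnames. Row
#'   names are metabolite ids, column names must equal `reaction_ids`.
#' @param reversible Logical vector, one entry per reaction.
#' @param internal_metabolites Character vector of internal metabolite ids.
#' @param external_metabolites Character vector of external metabolite ids;
#'   disjoint from the internal set.
#'
#' @return An object of class `network_model`.
#' @export
network_model <- function(reaction_ids, stoich, reversible,
                          internal_metabolites, external_metabolites) {
  reaction_ids <- as.character(reaction_ids)
  if (anyDuplicated(reaction_ids)) {
    stop("duplicate reaction ids: ",
         paste(unique(reaction_ids[duplicated(reaction_ids)]), collapse = ", "))
  }
  if (!is.matrix(stoich) || is.null(rownames(stoich)) || is.null(colnames(stoich))) {
    stop("stoich must be a matrix with metabolite row names and reaction column names")
  }
  if (!identical(colnames(stoich), reaction_ids)) {
    stop("stoich column names must match reaction_ids in order")
  }
  if (length(reversible) != length(reaction_ids)) {
    stop("reversible must have one entry per reaction")
  }
  mets <- rownames(stoich)
  if (anyDuplicated(mets)) stop("duplicate metabolite ids in stoich")
  both <- intersect(internal_metabolites, external_metabolites)
  if (length(both)) {
    stop("metabolite(s) declared both internal and external: ",
         paste(both, collapse = ", "))
  }
  undecl <- setdiff(mets, c(internal_metabolites, external_metabolites))
  if (length(undecl)) {
    stop("stoichiometry references undeclared metabolite(s): ",
         paste(undecl, collapse = ", "))
  }
  if (!all(is.finite(stoich))) stop("non-finite stoichiometric coefficient")
  structure(
    list(
      reaction_ids = reaction_ids,
      stoich = stoich,
      reversible = as.logical(reversible),
      internal_metabolites = as.character(internal_metabolites),
      external_metabolites = as.character(external_metabolites)
    ),
    class = "network_model"
  )
}

#' @export
print.network_model <- function(x, ...) {
  cat(sprintf(
    "Metabolic network: %d reactions (%d reversible), %d internal + %d external metabolites\n",
    length(x$reaction_ids), sum(x$reversible),
    length(x$internal_metabolites), length(x$external_metabolites)
  ))
  invisible(x)
}

# Parse one side of a reaction equation ("2 A + B") into coefficient/metabolite
# pairs. An empty side is allowed (pure source/sink steps).
parse_reaction_side <- function(txt, reaction, path_line) {
  txt <- trimws(txt)
  if (txt == "") return(list())
  terms <- strsplit(txt, "\\+")[[1]]
  out <- list()
  for (tm in terms) {
    tm <- trimws(tm)
    if (tm == "") {
      stop(sprintf("empty term in reaction '%s' (%s)", reaction, path_line))
    }
    parts <- strsplit(tm, "[[:space:]]+")[[1]]
    if (length(parts) == 1L) {
      coef <- 1
      met <- parts[1]
    } else if (length(parts) == 2L) {
      coef <- suppressWarnings(as.numeric(parts[1]))
      if (is.na(coef)) {
        stop(sprintf("non-numeric coefficient '%s' in reaction '%s' (%s)",
                     parts[1], reaction, path_line))
      }
      met <- parts[2]
    } else {
      stop(sprintf("cannot parse term '%s' in reaction '%s' (%s)",
                   tm, reaction, path_line))
    }
    out[[length(out) + 1L]] <- list(coef = coef, met = met)
  }
  out
}

#' Read a metabolic network in the Metatool sectioned text dialect
#'
#' The dialect consists of five headed sections, in any order:
#' \preformatted{
#' -ENZREV
#' <whitespace-separated reversible reaction names, possibly empty>
#' -ENZIRREV
#' <irreversible reaction names>
#' -METINT
#' <internal metabolite names>
#' -METEXT
#' <external metabolite names>
#' -CAT
#' <one line per reaction:  name : 1 A + 2 B = C .>
#' }
#' Coefficients default to 1; the trailing period is optional. Every reaction
#' named under `-ENZREV`/`-ENZIRREV` must have exactly one `-CAT` line and vice
#' versa; every metabolite used must be declared internal or external.
#' Reactions are ordered reversible block first, then irreversible, each in
#' declaration order, so downstream matrix columns are reproducible.
#'
#' @param path Path to the network file.
#' @return A validated [network_model()].
#' @export
read_metatool_network <- function(path) {
  if (!file.exists(path)) stop("network file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  # strip comments (# to end of line) and blank lines
  lines <- sub("#.*$", "", lines)
  keep <- which(trimws(lines) != "")
  lines <- lines[keep]
  headers <- c("-ENZREV", "-ENZIRREV", "-METINT", "-METEXT", "-CAT")
  idx <- which(trimws(lines) %in% headers)
  found <- trimws(lines)[idx]
  missing <- setdiff(headers, found)
  if (length(missing)) {
    stop("missing section header(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(found)) stop("duplicated section header(s)")
  bounds <- c(idx, length(lines) + 1L)
  sections <- list()
  for (k in seq_along(idx)) {
    body <- if (idx[k] + 1L <= bounds[k + 1L] - 1L) {
      lines[(idx[k] + 1L):(bounds[k + 1L] - 1L)]
    } else character(0)
    sections[[trimws(lines)[idx[k]]]] <- body
  }
  words <- function(v) {
    w <- unlist(strsplit(paste(v, collapse = " "), "[[:space:]]+"))
    w[w != ""]
  }
  enzrev <- words(sections[["-ENZREV"]])
  enzirrev <- words(sections[["-ENZIRREV"]])
  metint <- words(sections[["-METINT"]])
  metext <- words(sections[["-METEXT"]])
  reaction_ids <- c(enzrev, enzirrev)
  if (!length(reaction_ids)) stop("no reactions declared")
  reversible <- c(rep(TRUE, length(enzrev)), rep(FALSE, length(enzirrev)))

  cat_lines <- sections[["-CAT"]]
  eqs <- list()
  for (ln in cat_lines) {
    ln2 <- sub("\\.[[:space:]]*$", "", ln)
    colon <- regexpr(":", ln2, fixed = TRUE)
    if (colon < 0) stop("malformed -CAT line (no ':'): ", trimws(ln))
    rname <- trimws(substr(ln2, 1L, colon - 1L))
    body <- substr(ln2, colon + 1L, nchar(ln2))
    sides <- strsplit(body, "=", fixed = TRUE)[[1]]
    if (length(sides) != 2L) stop("malformed -CAT line (need one '='): ", trimws(ln))
    if (rname %in% names(eqs)) stop("duplicate -CAT entry for reaction: ", rname)
    eqs[[rname]] <- list(
      lhs = parse_reaction_side(sides[1], rname, path),
      rhs = parse_reaction_side(sides[2], rname, path)
    )
  }
  nocat <- setdiff(reaction_ids, names(eqs))
  if (length(nocat)) stop("reaction(s) without -CAT equation: ", paste(nocat, collapse = ", "))
  extra <- setdiff(names(eqs), reaction_ids)
  if (length(extra)) stop("-CAT equation(s) for undeclared reaction(s): ", paste(extra, collapse = ", "))

  mets <- c(metint, metext)
  if (anyDuplicated(mets)) {
    stop("metabolite(s) declared more than once: ",
         paste(unique(mets[duplicated(mets)]), collapse = ", "))
  }
  stoich <- matrix(0, nrow = length(mets), ncol = length(reaction_ids),
                   dimnames = list(mets, reaction_ids))
  for (rname in reaction_ids) {
    eq <- eqs[[rname]]
    for (term in eq$lhs) {
      if (!term$met %in% mets) {
        stop(sprintf("reaction '%s' references undeclared metabolite '%s'",
                     rname, term$met))
      }
      stoich[term$met, rname] <- stoich[term$met, rname] - term$coef
    }
    for (term in eq$rhs) {
      if (!term$met %in% mets) {
        stop(sprintf("reaction '%s' references undeclared metabolite '%s'",
                     rname, term$met))
      }
      stoich[term$met, rname] <- stoich[term$met, rname] + term$coef
    }
  }
  network_model(reaction_ids, stoich, reversible, metint, metext)
}

#' Write a network model in the Metatool sectioned dialect
#'
#' Inverse of [read_metatool_network()]: the emitted file parses back to an
#' equal model.
#'
#' @param network A [network_model()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_metatool_network <- function(network, path) {
  stopifnot(inherits(network, "network_model"))
  fmt_side <- function(coefs, mets) {
    if (!length(mets)) return("")
    paste(ifelse(coefs == 1, mets, paste(format(coefs, trim = TRUE), mets)),
          collapse = " + ")
  }
  cat_lines <- vapply(network$reaction_ids, function(rname) {
    col <- network$stoich[, rname]
    lhs <- which(col < 0)
    rhs <- which(col > 0)
    sprintf("%s : %s = %s .", rname,
            fmt_side(-col[lhs], rownames(network$stoich)[lhs]),
            fmt_side(col[rhs], rownames(network$stoich)[rhs]))
  }, character(1))
  out <- c(
    "-ENZREV", paste(network$reaction_ids[network$reversible], collapse = " "),
    "-ENZIRREV", paste(network$reaction_ids[!network$reversible], collapse = " "),
    "-METINT", paste(network$internal_metabolites, collapse = " "),
    "-METEXT", paste(network$external_metabolites, collapse = " "),
    "-CAT", cat_lines
  )
  writeLines(out, path)
  invisible(path)
}

#' Internal stoichiometric matrix of a network
#'
#' Restricts the stoichiometry to the internal (balanced) metabolites, whose
#' steady-state condition `N r = 0` defines the flux cone.
#'
#' @param network A [network_model()].
#' @return Numeric matrix, internal metabolites x reactions, rows in
#'   declaration order and columns in reaction order.
#' @export
build_internal_stoichiometry <- function(network) {
  stopifnot(inherits(network, "network_model"))
  if (!length(network$internal_metabolites)) {
    stop("network has no internal metabolites: no steady-state constraint to impose")
  }
  network$stoich[network$internal_metabolites, , drop = FALSE]
}
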