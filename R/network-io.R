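#' Read a reaction network from a reaction-table file
#'
#' Parses the plain-text tab-separated reaction-table dialect: a
#' \code{[species]} section with lines \code{name<TAB>init_conc_M<TAB>role}
#' (role \code{variable} or \code{constant}) followed by a \code{[reactions]}
#' section with lines \code{id<TAB>A + B -> C + D<TAB>k<TAB>tag}. Lines whose
#' first non-blank character is \code{#} are comments. Units are molar and
#' seconds (second-order rate constants in M^-1 s^-1). An empty product side
#' may be written as \code{0} (degradation to nothing); the reactant side must
#' contain one or two species (elementary reactions only). Parsing is
#' validated and lossless: [writeNetwork()] followed by [loadNetwork()]
#' reproduces the network.
#'
#' @param path path of the file to read.
#' @return A validated \linkS4class{ReactionNetwork}.
#' @examples
#' net <- loadNetwork(packagedNetworkPath())
#' nrow(reactions(net))  # 110
#' @seealso [packagedNetworkPath()] for the packaged signalling network.
#' @export
loadNetwork <- function(path) {
  if (!file.exists(path)) stop("network file not found: ", path)
  raw <- readLines(path, encoding = "UTF-8")
  lineno <- seq_along(raw)
  keep <- !grepl("^\\s*(#|$)", raw)
  lines <- raw[keep]
  lineno <- lineno[keep]

  perr <- function(i, ...) stop("parse error at line ", i, ": ", ...,
                                call. = FALSE)
  sec <- cumsum(grepl("^\\[", lines))
  hdrs <- trimws(lines[grepl("^\\[", lines)])
  if (!identical(hdrs, c("[species]", "[reactions]")))
    stop("file must contain a [species] section followed by [reactions]")
  body <- !grepl("^\\[", lines)

  sp_lines <- lines[sec == 1 & body]
  sp_nums <- lineno[sec == 1 & body]
  if (!length(sp_lines)) stop("empty species section")
  sp <- data.frame(name = character(), init_conc = numeric(),
                   role = character())
  for (i in seq_along(sp_lines)) {
    f <- strsplit(sp_lines[i], "\t", fixed = TRUE)[[1]]
    f <- trimws(f)
    if (length(f) != 3) perr(sp_nums[i], "expected 3 tab-separated fields")
    conc <- suppressWarnings(as.numeric(f[2]))
    if (is.na(conc)) perr(sp_nums[i], "unreadable concentration '", f[2], "'")
    if (conc < 0) perr(sp_nums[i], "negative concentration")
    if (!f[3] %in% c("variable", "constant"))
      perr(sp_nums[i], "role must be 'variable' or 'constant'")
    if (f[1] %in% sp$name) perr(sp_nums[i], "duplicate species '", f[1], "'")
    sp <- rbind(sp, data.frame(name = f[1], init_conc = conc, role = f[3]))
  }

  rx_lines <- lines[sec == 2 & body]
  rx_nums <- lineno[sec == 2 & body]
  if (!length(rx_lines)) stop("empty reactions section")
  ids <- character(length(rx_lines)); ks <- numeric(length(rx_lines))
  tags <- character(length(rx_lines))
  reac <- vector("list", length(rx_lines)); prod <- vector("list", length(rx_lines))
  for (i in seq_along(rx_lines)) {
    f <- strsplit(rx_lines[i], "\t", fixed = TRUE)[[1]]
    f <- trimws(f)
    if (length(f) < 3) perr(rx_nums[i], "expected at least 3 fields")
    sides <- strsplit(f[2], "->", fixed = TRUE)[[1]]
    if (length(sides) != 2) perr(rx_nums[i], "reaction must contain one '->'")
    parse_side <- function(s) {
      s <- trimws(s)
      if (s == "" || s == "0") return(character(0))
      trimws(strsplit(s, "+", fixed = TRUE)[[1]])
    }
    r <- parse_side(sides[1]); p <- parse_side(sides[2])
    if (length(r) < 1 || length(r) > 2)
      perr(rx_nums[i], "reactant order must be 1 or 2 (got ", length(r), ")")
    bad <- setdiff(c(r, p), sp$name)
    if (length(bad))
      perr(rx_nums[i], "unknown species '", bad[1], "'")
    k <- suppressWarnings(as.numeric(f[3]))
    if (is.na(k)) perr(rx_nums[i], "unreadable rate constant '", f[3], "'")
    if (k < 0) perr(rx_nums[i], "negative rate constant")
    ids[i] <- f[1]; ks[i] <- k
    tags[i] <- if (length(f) >= 4) f[4] else ""
    reac[[i]] <- r; prod[[i]] <- p
  }
  rx <- data.frame(id = ids, k = ks, tag = tags)
  rx$reactants <- reac
  rx$products <- prod
  rx <- rx[, c("id", "reactants", "products", "k", "tag")]
  new("ReactionNetwork", species = sp, reactions = rx)
}

#' Write a reaction network to a reaction-table file
#'
#' @param net a \linkS4class{ReactionNetwork}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @seealso [loadNetwork()]
#' @export
writeNetwork <- function(net, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("[species]", con)
  sp <- net@species
  writeLines(sprintf("%s\t%s\t%s", sp$name,
                     format(sp$init_conc, scientific = TRUE, digits = 15),
                     sp$role), con)
  writeLines("[reactions]", con)
  rx <- net@reactions
  side <- function(x) if (length(x)) paste(x, collapse = " + ") else "0"
  writeLines(sprintf("%s\t%s -> %s\t%s\t%s", rx$id,
                     vapply(rx$reactants, side, ""),
                     vapply(rx$products, side, ""),
                     format(rx$k, scientific = FALSE, digits = 15), rx$tag),
             con)
  invisible(path)
}

#' Path of the packaged signal transduction network
#'
#' Returns the installed path of the packaged reaction-table file for the
#' 66-species, 110-reaction network combining the PKC, MAPK, PLA2 and
#' PLC-beta signalling modules (a synthetic reconstruction of the Bhalla &
#' Iyengar 1999 mass-action scheme; see the file header and the package
#' vignette for provenance). Five species (APC, tempPIP2, Inositol, PC, PIP2)
#' are constant model inputs; the other 61 are model variables.
#'
#' @return character path.
#' @examples
#' net <- loadNetwork(packagedNetworkPath())
#' @export
packagedNetworkPath <- function() {
  system.file("extdata", "pkc_mapk_pla2_plcb_synthetic.tsv",
              package = "brnnoise", mustWork = TRUE)
}
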