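# Builders and independent oracles used across test files.

# construct a ReactionNetwork in code (no file round-trip)
mkNetwork <- function(species, rxns) {
  rx <- data.frame(id = vapply(rxns, `[[`, "", "id"),
                   k = vapply(rxns, `[[`, 0, "k"),
                   tag = vapply(rxns, function(r) r$tag %||% "", ""))
  rx$reactants <- lapply(rxns, `[[`, "r")
  rx$products <- lapply(rxns, `[[`, "p")
  rx <- rx[, c("id", "reactants", "products", "k", "tag")]
  new("ReactionNetwork", species = species, reactions = rx)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent O(N^2) direct-sum DFT
directDFT <- function(x) {
  N <- length(x)
  vapply(0:(N - 1), function(k)
    sum(x * exp(-2i * pi * k * (0:(N - 1)) / N)), complex(1))
}

# write a reaction-table file from text lines
writeTableFile <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}

AVOGADRO <- 6.02214076e23
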