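# Internal helpers shared across modules.

# Fixed palette for deterministic module naming; assigned by descending
# module size, "grey" is reserved for unassigned genes.
.module_palette <- c(
  "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
  "magenta", "purple", "greenyellow", "tan", "salmon", "cyan", "midnightblue",
  "lightcyan", "grey60", "lightgreen", "lightyellow", "royalblue", "darkred",
  "darkgreen", "darkturquoise", "darkgrey", "orange", "darkorange", "white",
  "skyblue", "saddlebrown", "steelblue", "paleturquoise", "violet",
  "darkolivegreen", "darkmagenta", "sienna3", "yellowgreen", "skyblue3",
  "plum1", "orangered4", "mediumpurple3", "lightsteelblue1", "lightcyan1",
  "ivory", "floralwhite", "darkorange2", "brown4", "bisque4", "darkslateblue",
  "plum2", "thistle2"
)

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.check_numeric_vector <- function(x, name, n = NULL) {
  if (!is.numeric(x)) .stopf("'%s' must be numeric", name)
  if (!is.null(n) && length(x) != n)
    .stopf("'%s' must have length %d (got %d)", name, n, length(x))
  invisible(x)
}

.is_constant <- function(x, tol = 1e-12) {
  stats::var(x) < tol || !is.finite(stats::var(x))
}

# Numeric coding of RIS genotypes: A = 0, B = 1.
.geno_numeric <- function(genotypes) {
  codes <- genotypes$codes
  x <- (codes == "B") * 1
  dimnames(x) <- dimnames(codes)
  storage.mode(x) <- "double"
  x
}

.seed_from <- function(seed, offset = 0L) {
  as.integer((as.numeric(seed) + offset) %% .Machine$integer.max)
}
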