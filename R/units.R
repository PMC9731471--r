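#' Convert a concentration to molar
#'
#' Internal unit system is molar and seconds throughout the package; this
#' helper converts the micro/nano-molar values quoted in typical receptor
#' pharmacology into molar.
#'
#' @param x numeric concentration value(s).
#' @param unit one of `"M"`, `"mM"`, `"uM"`, `"nM"`, `"pM"`.
#' @return numeric, concentration in molar.
#' @examples
#' molar(1, "uM")   # 1e-6
#' @export
molar <- function(x, unit = c("M", "mM", "uM", "nM", "pM")) {
  unit <- match.arg(unit)
  scale <- c(M = 1, mM = 1e-3, uM = 1e-6, nM = 1e-9, pM = 1e-12)[[unit]]
  x * scale
}

## parse strings such as "1uM", "250 nM", "2e-6" (bare numbers are molar)
parse_conc <- function(s) {
  if (is.numeric(s)) return(as.numeric(s))
  s <- trimws(s)
  m <- regmatches(s, regexec("^([-+0-9.eE]+)\\s*(M|mM|uM|nM|pM)?$", s))[[1]]
  if (length(m) == 0L || m[2] == "") {
    stop("cannot parse concentration: '", s, "'")
  }
  unit <- if (m[3] == "") "M" else m[3]
  molar(as.numeric(m[2]), unit)
}
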