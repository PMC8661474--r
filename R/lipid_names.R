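#' Parse a lipid shorthand name
#'
#' Understands the common sum-composition and chain-level shorthand used for
#' plasma lipidomics, e.g. `"TG (16:0/18:0/18:1)"`, `"PC (O-34:3)"`,
#' `"Cer (d18:1/23:0)"`.  The class token before the parenthesis maps to a
#' lipid class; `C:D` tokens give carbons and double bonds; `/`-separated
#' chains are summed into totals; an `O-`/`P-` prefix marks an alkyl or
#' alkenyl (plasmalogen) ether bond.  Dual-identity names such as
#' `"PE (O-38:5) or PE (P-38:4)"` are resolved from the first alternative,
#' with the full string kept in `raw_name`.  Whitespace is insignificant.
#'
#' The parser is total: any name it cannot understand yields
#' `lipid_class = "unknown"` with zero totals — never an error.
#'
#' @param name lipid name, non-empty string.
#' @return list with `lipid_class`, `total_carbons`, `total_double_bonds`,
#'   `ether_flag` ("none", "O" or "P"), `chains` (list of `c(carbons, dbs)`
#'   or NULL when only a sum composition is given) and `raw_name`.
#' @examples
#' parse_lipid_name("TG (16:0/18:0/18:1)")  # class TG, 52:1
#' parse_lipid_name("PC (O-34:3)")          # ether PC, 34:3
#' @export
parse_lipid_name <- function(name) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  unknown <- list(lipid_class = "unknown", total_carbons = 0L,
                  total_double_bonds = 0L, ether_flag = "none",
                  chains = NULL, raw_name = name)
  # first alternative of a dual-identity name
  first <- strsplit(name, "\\s+or\\s+")[[1L]][1L]
  s <- gsub("\\s+", "", first)
  m <- regmatches(s, regexec("^([A-Za-z]+)\\(([^()]*)\\)$", s))[[1L]]
  if (length(m) != 3L) return(unknown)
  cls_map <- c(tg = "TG", pc = "PC", lpc = "LPC", pe = "PE", lpe = "LPE",
               pi = "PI", cer = "Cer", sm = "SM", choe = "ChoE")
  cls <- cls_map[tolower(m[2L])]
  if (is.na(cls)) return(unknown)
  body <- m[3L]
  ether <- "none"
  em <- regmatches(body, regexec("^([OP])-(.*)$", body))[[1L]]
  if (length(em) == 3L) {
    ether <- em[2L]
    body <- em[3L]
  }
  glycerophospholipids <- c("PC", "LPC", "PE", "LPE", "PI")
  if (ether != "none" && !(cls %in% glycerophospholipids)) return(unknown)
  toks <- strsplit(body, "/", fixed = TRUE)[[1L]]
  if (!length(toks)) return(unknown)
  chains <- lapply(toks, function(tok) {
    # sphingoid-base prefixes (d18:1, t18:0) carry a leading letter
    cm <- regmatches(tok, regexec("^[a-z]?([0-9]+):([0-9]+)$", tok))[[1L]]
    if (length(cm) != 3L) return(NULL)
    c(carbons = as.integer(cm[2L]), double_bonds = as.integer(cm[3L]))
  })
  if (any(vapply(chains, is.null, logical(1)))) return(unknown)
  total_c <- sum(vapply(chains, `[[`, integer(1), "carbons"))
  total_d <- sum(vapply(chains, `[[`, integer(1), "double_bonds"))
  list(lipid_class = unname(cls),
       total_carbons = as.integer(total_c),
       total_double_bonds = as.integer(total_d),
       ether_flag = ether,
       chains = if (length(chains) > 1L) chains else NULL,
       raw_name = name)
}
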