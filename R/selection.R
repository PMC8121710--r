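# Atom selection mini-grammar.
#
#   expr    := term ('or' term)*
#   term    := factor ('and' factor)*
#   factor  := 'not' factor | '(' expr ')' | keyword values | 'all' |
#              'backbone' | 'hydrogen'
#   keyword := chain | resid | resno | resname | name | elety | element
#   values  := item (',' item)*        item := token | lo ':' hi   (numeric)
#
# Evaluation is a logical mask over the atom table, so selections are
# deterministic and order-preserving regardless of how the expression is
# phrased.

.backbone_names <- c("P", "OP1", "OP2", "O5'", "C5'", "C4'", "C3'", "O3'",
                     "O4'", "C1'", "C2'", "O2'",  # nucleic backbone + sugar
                     "N", "CA", "C", "O")         # protein backbone

.tokenize_selection <- function(expression) {
  expression <- gsub("([()])", " \\1 ", expression)
  tokens <- strsplit(trimws(expression), "[[:space:]]+")[[1]]
  tokens[nzchar(tokens)]
}

.parse_values <- function(token, numeric) {
  items <- strsplit(token, ",", fixed = TRUE)[[1]]
  out <- lapply(items, function(it) {
    if (numeric && grepl("^-?[0-9]+:-?[0-9]+$", it)) {
      r <- as.integer(strsplit(it, ":", fixed = TRUE)[[1]])
      seq(r[1], r[2])
    } else if (numeric) {
      v <- suppressWarnings(as.integer(it))
      if (is.na(v)) stop("expected a number in selection, got '", it, "'")
      v
    } else it
  })
  unlist(out)
}

.select_keywords <- c("chain", "resid", "resno", "resname", "name", "elety",
                      "element")

.eval_selection <- function(tokens, atoms) {
  pos <- 1L
  peek <- function() if (pos <= length(tokens)) tokens[pos] else NA_character_
  advance <- function() { tok <- tokens[pos]; pos <<- pos + 1L; tok }

  parse_factor <- function() {
    tok <- peek()
    if (is.na(tok)) stop("unexpected end of selection expression")
    if (tok == "not") { advance(); return(!parse_factor()) }
    if (tok == "(") {
      advance()
      m <- parse_expr()
      if (!identical(peek(), ")")) stop("missing ')' in selection")
      advance()
      return(m)
    }
    if (tok == "all") { advance(); return(rep(TRUE, nrow(atoms))) }
    if (tok == "backbone") { advance(); return(atoms$name %in% .backbone_names) }
    if (tok == "hydrogen") { advance(); return(toupper(atoms$element) == "H") }
    if (tok %in% .select_keywords) {
      advance()
      value_tok <- advance()
      if (is.na(value_tok)) stop("keyword '", tok, "' needs a value")
      switch(tok,
        chain = atoms$chain %in% .parse_values(value_tok, FALSE),
        resid = ,
        resno = atoms$resno %in% .parse_values(value_tok, TRUE),
        resname = atoms$resname %in% .parse_values(value_tok, FALSE),
        name = ,
        elety = atoms$name %in%
          normalize_atom_name(.parse_values(value_tok, FALSE)),
        element = toupper(atoms$element) %in%
          toupper(.parse_values(value_tok, FALSE)))
    } else stop("unrecognised selection token '", tok, "'")
  }
  parse_term <- function() {
    m <- parse_factor()
    while (identical(peek(), "and")) { advance(); m <- m & parse_factor() }
    m
  }
  parse_expr <- function() {
    m <- parse_term()
    while (identical(peek(), "or")) { advance(); m <- m | parse_term() }
    m
  }
  m <- parse_expr()
  if (pos <= length(tokens))
    stop("trailing tokens in selection: ",
         paste(tokens[pos:length(tokens)], collapse = " "))
  m
}

#' Select atoms by expression
#'
#' Evaluates a small boolean selection grammar over the atom table:
#' keywords `chain`, `resid`/`resno`, `resname`, `name`/`elety`, `element`
#' with comma-separated values and `lo:hi` ranges, combined with `and`,
#' `or`, `not` and parentheses; plus the shortcuts `all`, `backbone` and
#' `hydrogen`.  E.g. `"chain R and resid 13 and name N6"` or
#' `"resid 1,4,7,10,13,16 and name C1'"`.
#'
#' @param topology a [topology()] object.
#' @param expression selection text in the grammar above.
#' @return An `AtomSelection`: an integer vector of atom indices in topology
#'   order (never duplicated), with the source expression attached.  A
#'   selection matching nothing returns an empty vector with a warning, not
#'   an error.
#' @export
select_atoms <- function(topology, expression) {
  stopifnot(inherits(topology, "Topology"))
  mask <- .eval_selection(.tokenize_selection(expression), topology$atoms)
  idx <- which(mask)
  if (length(idx) == 0L)
    warning("selection '", expression, "' matched no atoms")
  structure(idx, expression = expression, class = "AtomSelection")
}

#' Address a single atom by residue identity and name
#'
#' @param topology a [topology()] object.
#' @param resno residue number.
#' @param name atom name (PDB v3; legacy names are normalised).
#' @param chain chain identifier, or `NULL` to match any chain.
#' @param insert insertion code, default none.
#' @return The atom's index (integer of length 1); error if the address is
#'   missing or ambiguous.
#' @export
atom_index <- function(topology, resno, name, chain = NULL, insert = "") {
  at <- topology$atoms
  name <- normalize_atom_name(name)
  hit <- at$resno == resno & at$name == name &
    ifelse(is.na(at$insert), "", at$insert) == insert
  if (!is.null(chain)) hit <- hit & at$chain == chain
  idx <- which(hit)
  if (length(idx) == 0L)
    stop("no atom '", name, "' in residue ",
         if (is.null(chain)) "" else paste0(chain, ":"), resno)
  if (length(idx) > 1L)
    stop("ambiguous atom address: residue ", resno, " atom ", name,
         " (specify chain)")
  idx
}
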