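#' Behavioral state spaces and coding schemes
#'
#' A coding scheme bundles an ordered state space, per-taxon state codings
#' (possibly polymorphic), and a transition-constraint mask (structural zeros
#' of the rate matrix). Two built-ins cover the social-level characters:
#'
#' * `"traditional"`: four states `Sol`, `Prim`, `Adv`, `Paras`
#'   (solitary, primitively eusocial, advanced eusocial, parasitic).
#'   Forbidden transitions: `Sol->Adv`, `Paras->Adv` (no jump to
#'   morphologically differentiated castes without an intermediate step) and
#'   every transition out of `Adv` (advanced eusociality is absorbing:
#'   queens cannot found nests independently of workers).
#' * `"complex"`: adds a fifth state `Soc` (social: subsocial/parasocial
#'   organization) between `Sol` and `Prim`; the same two rules apply and
#'   nothing further is forbidden.
#'
#' Binary life-history traits use `lifehistory_scheme()`: states `absent`,
#' `present`, full mask, reversible-jump flag on.
#'
#' Polymorphic codings carry ambiguity semantics (the taxon is in one of the
#' listed states, which one unknown), not frequency semantics.
#'
#' @param states ordered character vector of state names (length >= 2).
#' @param forbidden character vector of forbidden transitions written
#'   `"From->To"`; everything else (off-diagonal) is allowed.
#' @param tips named list mapping taxon labels to character vectors of state
#'   names, or a trait tibble as returned by [read_traits()].
#' @param rj logical: sample rate-class structure by reversible jump.
#' @param name scheme name.
#' @param symbols single-character symbols used in trait files, one per state.
#' @return an object of class `coding_scheme`.
#' @export
coding_scheme <- function(states, forbidden = character(), tips = NULL,
                          rj = FALSE, name = "custom", symbols = NULL) {
  assert_that(is.character(states) && length(states) >= 2 &&
                anyDuplicated(states) == 0,
              "states must be >= 2 unique names")
  k <- length(states)
  if (is.null(symbols)) symbols <- default_symbols(states)
  assert_that(length(symbols) == k && all(nchar(symbols) == 1) &&
                anyDuplicated(symbols) == 0,
              "symbols must be unique single characters, one per state")
  mask <- matrix(TRUE, k, k, dimnames = list(states, states))
  diag(mask) <- FALSE
  for (f in forbidden) {
    ft <- strsplit(f, "->", fixed = TRUE)[[1]]
    if (length(ft) != 2 || !all(ft %in% states)) {
      abort(sprintf("malformed forbidden transition '%s' (use \"From->To\" with known states)", f))
    }
    mask[ft[1], ft[2]] <- FALSE
  }
  scheme <- structure(
    list(name = name, states = states, symbols = setNames(symbols, states),
         mask = mask, tips = list(), rj = isTRUE(rj)),
    class = "coding_scheme")
  if (!is.null(tips)) scheme <- set_tips(scheme, tips)
  scheme
}

# Global trait-file symbol convention: 0=Sol, 1=Soc, 2=Prim, 3=Adv, 4=Paras;
# binary traits 0=absent, 1=present; anything else gets 0..k-1 in state order.
default_symbols <- function(states) {
  known <- c(Sol = "0", Soc = "1", Prim = "2", Adv = "3", Paras = "4",
             absent = "0", present = "1")
  if (all(states %in% names(known))) unname(known[states])
  else as.character(seq_along(states) - 1L)
}

#' @export
print.coding_scheme <- function(x, ...) {
  cat(sprintf("<coding_scheme> %s: %d states (%s), %d/%d transitions allowed, %d coded taxa%s\n",
              x$name, length(x$states), paste(x$states, collapse = ", "),
              sum(x$mask), length(x$states) * (length(x$states) - 1),
              length(x$tips), if (x$rj) ", reversible-jump" else ""))
  invisible(x)
}

#' Built-in social-level coding schemes
#'
#' @param name `"traditional"` or `"complex"` (see [coding_scheme()] for the
#'   state spaces and constraint rules).
#' @param tips optional per-taxon codings to attach.
#' @return a `coding_scheme`.
#' @export
builtin_scheme <- function(name = c("traditional", "complex"), tips = NULL) {
  name <- match.arg(name)
  states <- if (name == "complex") {
    c("Sol", "Soc", "Prim", "Adv", "Paras")
  } else {
    c("Sol", "Prim", "Adv", "Paras")
  }
  # rule 1: no direct gain of advanced eusociality from solitary or parasitic
  # rule 2: advanced eusociality is absorbing
  forbidden <- c("Sol->Adv", "Paras->Adv",
                 paste0("Adv->", setdiff(states, "Adv")))
  coding_scheme(states, forbidden = forbidden, tips = tips, rj = FALSE,
                name = name)
}

#' Binary life-history trait scheme
#'
#' States `absent`/`present`, full transition mask, reversible jump on.
#'
#' @param trait trait name (e.g. `"mass provisioning"`).
#' @param tips optional per-taxon codings.
#' @return a `coding_scheme` with `rj = TRUE`.
#' @export
lifehistory_scheme <- function(trait, tips = NULL) {
  coding_scheme(c("absent", "present"), character(), tips = tips, rj = TRUE,
                name = paste0("lifehistory:", trait))
}

#' Attach per-taxon codings to a scheme
#'
#' @param scheme a `coding_scheme`.
#' @param tips named list of state-name vectors, or a tibble with columns
#'   `taxon` and `symbols` (single-character codes concatenated for
#'   polymorphic codings; `"-"` = fully ambiguous).
#' @return the scheme with `$tips` filled.
#' @export
set_tips <- function(scheme, tips) {
  if (is.data.frame(tips)) {
    tips <- setNames(lapply(tips$symbols, symbols_to_states, scheme = scheme),
                     tips$taxon)
  } else {
    tips <- lapply(tips, function(st) {
      if (length(st) == 1 && !st %in% scheme$states) {
        return(symbols_to_states(st, scheme))
      }
      bad <- setdiff(st, scheme$states)
      if (length(bad) > 0) {
        abort(sprintf("unknown state name(s): %s", paste(bad, collapse = ", ")))
      }
      st
    })
  }
  empty <- names(tips)[lengths(tips) == 0]
  if (length(empty) > 0) {
    abort(sprintf("empty codings for: %s", paste(empty, collapse = ", ")))
  }
  scheme$tips <- tips
  scheme
}

symbols_to_states <- function(symbols, scheme) {
  if (identical(symbols, "-")) return(scheme$states)
  chars <- strsplit(symbols, "")[[1]]
  idx <- match(chars, scheme$symbols)
  if (anyNA(idx)) {
    abort(sprintf("unknown state symbol(s) '%s' for scheme %s (known: %s)",
                  paste(chars[is.na(idx)], collapse = ""), scheme$name,
                  paste(scheme$symbols, collapse = "")))
  }
  scheme$states[sort(unique(idx))]
}

states_to_symbols <- function(states, scheme) {
  paste(scheme$symbols[states], collapse = "")
}

#' Read / write BayesTraits-style trait files
#'
#' Two tab-separated columns, no header: taxon label and concatenated
#' single-character state symbols (`"02"` = polymorphic; `"-"` = fully
#' ambiguous).
#'
#' @param path trait file.
#' @return `read_traits`: a tibble with columns `taxon`, `symbols`.
#' @export
read_traits <- function(path) {
  assert_that(file.exists(path), sprintf("file not found: %s", path))
  df <- readr::read_tsv(path, col_names = c("taxon", "symbols"),
                        col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  if (anyDuplicated(df$taxon) > 0) {
    abort(sprintf("duplicate taxa in trait file: %s",
                  paste(unique(df$taxon[duplicated(df$taxon)]), collapse = ", ")))
  }
  df
}

#' @rdname read_traits
#' @param traits tibble with columns `taxon`, `symbols`, or a `coding_scheme`
#'   with tips attached.
#' @param scheme scheme used to translate state names to symbols when
#'   `traits` is a scheme.
#' @export
write_traits <- function(traits, path, scheme = NULL) {
  if (inherits(traits, "coding_scheme")) {
    scheme <- traits
    traits <- tibble(
      taxon = names(scheme$tips),
      symbols = purrr::map_chr(scheme$tips, states_to_symbols, scheme = scheme))
  }
  readr::write_tsv(traits[, c("taxon", "symbols")], path, col_names = FALSE)
  invisible(path)
}

#' Per-tip partial likelihood vector (ambiguity coding)
#'
#' Length-k indicator vector with 1 at each state the taxon may occupy and 0
#' elsewhere. A fully ambiguous taxon (all ones) contributes no information.
#'
#' @param scheme a `coding_scheme` with tips attached.
#' @param taxon taxon label.
#' @return named numeric vector over the scheme's states.
#' @export
tip_partial <- function(scheme, taxon) {
  if (!taxon %in% names(scheme$tips)) {
    abort(sprintf("taxon '%s' has no coding in scheme %s", taxon, scheme$name))
  }
  as.numeric(scheme$states %in% scheme$tips[[taxon]]) |>
    setNames(scheme$states)
}

# k x n matrix of tip partials, columns ordered as `taxa`; errors list all
# uncoded taxa at once.
tip_partial_matrix <- function(scheme, taxa) {
  missing <- setdiff(taxa, names(scheme$tips))
  if (length(missing) > 0) {
    abort(sprintf("taxa present in tree but absent from coding: %s",
                  paste(missing, collapse = ", ")))
  }
  vapply(taxa, function(tx) tip_partial(scheme, tx),
         numeric(length(scheme$states)))
}

#' Check that observed tip states are reachable under the constraint mask
#'
#' Warns if any state observed at the tips cannot be reached, along the
#' mask's directed transition graph, from any state with positive root prior
#' (such data force a zero likelihood).
#'
#' @param scheme a `coding_scheme`.
#' @param root_prior probability vector over states (default uniform).
#' @return tibble with columns `state`, `observed`, `reachable`, invisibly
#'   returned after emitting any warnings.
#' @export
validate_reachability <- function(scheme, root_prior = NULL) {
  k <- length(scheme$states)
  if (is.null(root_prior)) root_prior <- rep(1 / k, k)
  assert_that(length(root_prior) == k && all(root_prior >= 0) &&
                abs(sum(root_prior) - 1) < 1e-8,
              "root_prior must be a probability vector over the states")
  reach <- root_prior > 0
  repeat {
    nxt <- reach | (as.vector(reach %*% scheme$mask) > 0)
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  observed <- scheme$states %in% unique(unlist(scheme$tips))
  report <- tibble(state = scheme$states, observed = observed, reachable = reach)
  bad <- report$state[report$observed & !report$reachable]
  if (length(bad) > 0) {
    warn(sprintf(
      "observed tip state(s) unreachable from the root prior under the mask: %s (likelihood will be 0)",
      paste(bad, collapse = ", ")))
  }
  invisible(report)
}

#' Read / write a coding scheme as structured text (YAML)
#'
#' Keys: `builtin` (optional, `"traditional"`/`"complex"`), `name`, `states`,
#' `forbidden` (list of `"From->To"`), `tips` (taxon: symbol string), `rj`.
#'
#' @param path scheme file.
#' @return `read_scheme`: a `coding_scheme`.
#' @export
read_scheme <- function(path) {
  cfg <- yaml::read_yaml(path)
  scheme <- if (!is.null(cfg$builtin)) {
    builtin_scheme(cfg$builtin)
  } else if (!is.null(cfg$lifehistory)) {
    lifehistory_scheme(cfg$lifehistory)
  } else {
    coding_scheme(as.character(cfg$states),
                  forbidden = as.character(cfg$forbidden %||% character()),
                  rj = isTRUE(cfg$rj),
                  name = cfg$name %||% "custom")
  }
  if (isTRUE(cfg$rj)) scheme$rj <- TRUE
  if (length(cfg$tips) > 0) {
    scheme <- set_tips(scheme, tibble(taxon = names(cfg$tips),
                                      symbols = as.character(unlist(cfg$tips))))
  }
  scheme
}

#' @rdname read_scheme
#' @param scheme a `coding_scheme`.
#' @export
write_scheme <- function(scheme, path) {
  forb <- which(!scheme$mask & !diag(TRUE, length(scheme$states)), arr.ind = TRUE)
  cfg <- list(
    name = scheme$name,
    states = as.list(scheme$states),
    forbidden = as.list(paste0(scheme$states[forb[, 1]], "->",
                               scheme$states[forb[, 2]])),
    rj = scheme$rj,
    tips = lapply(scheme$tips, states_to_symbols, scheme = scheme))
  yaml::write_yaml(cfg, path)
  invisible(path)
}
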