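#' Route vocabulary and risky-route classification
#'
#' Administration routes are a closed, configurable vocabulary. A route is
#' "risky" when it appears on the packaged list of invasive or error-prone
#' administration types, or when its token carries the prefix \code{intra-}
#' (intravenous, intrathecal, intraarticular, ...). Tokens are normalised by
#' lowercasing and stripping hyphens, spaces and underscores before lookup, so
#' \code{"Sub-tenon"}, \code{"sub tenon"} and \code{"subtenon"} are the same
#' route.
#'
#' @param path Path to a JSON vocabulary file with fields \code{vocabulary},
#'   \code{risky} and \code{risky_prefixes}. Defaults to the vocabulary
#'   shipped with the package.
#' @return A \code{route_vocabulary} object (a list with normalised
#'   \code{vocabulary}, \code{risky} and \code{risky_prefixes} character
#'   vectors).
#' @export
route_vocabulary <- function(path = system.file("extdata", "routes.json",
                                                package = "rxaudit")) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("vocabulary", "risky", "risky_prefixes")) {
    if (is.null(raw[[f]])) stop("route vocabulary file lacks field '", f, "'")
  }
  vocab <- list(
    vocabulary     = unique(normalize_route(raw$vocabulary)),
    risky          = unique(normalize_route(raw$risky)),
    risky_prefixes = unique(normalize_route(raw$risky_prefixes))
  )
  extra <- setdiff(vocab$risky, vocab$vocabulary)
  if (length(extra) > 0)
    stop("risky routes not in vocabulary: ", paste(extra, collapse = ", "))
  class(vocab) <- "route_vocabulary"
  vocab
}

# lowercase, strip hyphens / spaces / underscores
normalize_route <- function(x) gsub("[-_ ]", "", tolower(trimws(x)))

#' Validate route tokens against the vocabulary
#'
#' @param route Character vector of route tokens.
#' @param vocab A \code{route_vocabulary}.
#' @return The normalised tokens, invisibly usable downstream.
#' @export
validate_route <- function(route, vocab = route_vocabulary()) {
  r <- normalize_route(route)
  bad <- unique(route[!(r %in% vocab$vocabulary)])
  if (length(bad) > 0)
    stop("unknown administration route token(s): ", paste(bad, collapse = ", "))
  r
}

#' Is an administration route classified as risky?
#'
#' Vectorised. A route is risky when it is on the configured risky list or
#' starts with a risky prefix (by default \code{intra}).
#'
#' @inheritParams validate_route
#' @return Logical vector.
#' @examples
#' vocab <- route_vocabulary()
#' is_risky_route(c("subcutaneous", "peroral", "intrathecal"), vocab)
#' @export
is_risky_route <- function(route, vocab = route_vocabulary()) {
  r <- validate_route(route, vocab)
  risky <- r %in% vocab$risky
  for (p in vocab$risky_prefixes) risky <- risky | startsWith(r, p)
  risky
}

#' Categorize prescriptions
#'
#' Every prescription falls in exactly one of four categories. Orders given
#' "as needed" form their own category regardless of route; regular orders are
#' split into standard peroral, risky-route, and other by their administration
#' route.
#'
#' @param route Character vector of route tokens.
#' @param as_needed Logical vector, same length.
#' @param vocab A \code{route_vocabulary}.
#' @return Factor with levels \code{STANDARD_PERORAL}, \code{RISKY_ROUTE},
#'   \code{AS_NEEDED}, \code{OTHER}.
#' @export
categorize_prescription <- function(route, as_needed, vocab = route_vocabulary()) {
  stopifnot(length(route) == length(as_needed), is.logical(as_needed))
  if (anyNA(as_needed)) stop("as_needed must be TRUE or FALSE, not missing")
  r <- validate_route(route, vocab)
  out <- rep("OTHER", length(r))
  out[r == "peroral"] <- "STANDARD_PERORAL"
  out[is_risky_route(route, vocab)] <- "RISKY_ROUTE"
  out[as_needed] <- "AS_NEEDED"
  factor(out, levels = prescription_categories())
}

#' The four prescription categories, in reporting order
#' @return Character vector of category labels.
#' @export
prescription_categories <- function() {
  c("STANDARD_PERORAL", "RISKY_ROUTE", "AS_NEEDED", "OTHER")
}
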