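#' Rule configuration for the certificate error detectors
#'
#' A `rule_config` bundles the lexical knowledge the detectors rely on:
#' the ill-defined-condition lexicon, abbreviation lists, conjunction tokens,
#' the condition-category map with its acyclic cause-to-consequence relation,
#' and the qualifier lexicons used by the under-specified-diagnosis rules.
#' The default configuration ships with the package as a YAML file and can be
#' overridden wholesale or field by field.
#'
#' @param fields named list with the fields of the shipped YAML schema (see
#'   `system.file("extdata", "default_rules.yaml", package = "certaudit")`).
#' @return an object of class `rule_config`.
#' @export
rule_config <- function(fields) {
  stopifnot(is.list(fields))
  required <- c(
    "conjunction_tokens", "ill_defined_lexicon", "abbreviation_lexicon",
    "abbreviation_whitelist", "categories", "causal_relation",
    "non_initiating_categories", "external_cause_terms", "intent_terms",
    "mechanism_terms", "neoplasm_terms", "neoplasm_behaviour_terms",
    "neoplasm_site_terms", "hypertension_terms", "hypertension_qualifiers",
    "diabetes_terms", "diabetes_qualifiers", "ucod_capable_terms"
  )
  missing <- setdiff(required, names(fields))
  if (length(missing) > 0L) {
    stop("rule_config is missing fields: ", paste(missing, collapse = ", "))
  }
  cfg <- fields[required]
  for (f in setdiff(required, c("categories", "causal_relation"))) {
    cfg[[f]] <- normalize_text(unlist(cfg[[f]], use.names = FALSE))
    if (length(cfg[[f]]) == 0L && f != "abbreviation_whitelist") {
      stop("rule_config field '", f, "' must be non-empty")
    }
  }

  terms <- normalize_text(names(fields$categories))
  cats <- unlist(fields$categories, use.names = FALSE)
  if (anyDuplicated(terms)) stop("duplicate terms in category map")
  cfg$categories <- stats::setNames(cats, terms)

  rel <- fields$causal_relation
  if (is.list(rel)) rel <- do.call(rbind, lapply(rel, unlist))
  rel <- matrix(as.character(rel), ncol = 2L)
  all_cats <- sort(unique(c(cats, rel)))
  adj <- matrix(FALSE, length(all_cats), length(all_cats),
                dimnames = list(all_cats, all_cats))
  adj[cbind(match(rel[, 1L], all_cats), match(rel[, 2L], all_cats))] <- TRUE

  # Reachability by iterated squaring; a cycle shows up on the diagonal.
  reach <- adj
  repeat {
    nxt <- reach | ((reach %*% reach) > 0)
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  if (any(diag(reach))) {
    bad <- all_cats[diag(reach)]
    stop("causal_relation contains a cycle through: ",
         paste(bad, collapse = ", "))
  }
  closure <- reach
  diag(closure) <- TRUE # same-category progression is always accepted
  cfg$causal_relation <- rel
  cfg$closure <- closure

  unknown <- setdiff(cfg$non_initiating_categories, all_cats)
  if (length(unknown) > 0L) {
    stop("non_initiating_categories not in category vocabulary: ",
         paste(unknown, collapse = ", "))
  }
  cfg$version <- fields$version %||% 1L
  structure(cfg, class = "rule_config")
}

#' @export
print.rule_config <- function(x, ...) {
  cat("<rule_config v", x$version, ">\n", sep = "")
  cat("  ill-defined terms:   ", length(x$ill_defined_lexicon), "\n")
  cat("  abbreviations:       ", length(x$abbreviation_lexicon), "\n")
  cat("  mapped conditions:   ", length(x$categories), "\n")
  cat("  condition categories:", ncol(x$closure), "\n")
  cat("  causal pairs:        ", nrow(x$causal_relation), "\n")
  invisible(x)
}

#' Read a rule configuration from a YAML file
#'
#' @param path path to a YAML file with the shipped schema.
#' @return a [rule_config()] object.
#' @export
read_rule_config <- function(path) {
  if (!file.exists(path)) stop("rule configuration file not found: ", path)
  rule_config(yaml::read_yaml(path))
}

#' Write a rule configuration to a YAML file
#'
#' Round-trips through [read_rule_config()].
#'
#' @param config a [rule_config()] object.
#' @param path output path.
#' @export
write_rule_config <- function(config, path) {
  stopifnot(inherits(config, "rule_config"))
  out <- unclass(config)
  out$closure <- NULL
  out$categories <- as.list(out$categories)
  out$causal_relation <- lapply(seq_len(nrow(config$causal_relation)),
                                function(i) as.list(config$causal_relation[i, ]))
  yaml::write_yaml(out, path)
  invisible(path)
}

#' The default shipped rule configuration
#'
#' Spanish-language lexicons (with a few English aliases) built around the
#' published error taxonomy: modes of dying, organ failures, symptoms and
#' shock as ill-defined causes; a ~15-category condition map with an acyclic
#' cause-to-consequence relation for sequence checking; and the qualifier
#' rules for external causes, neoplasms, hypertension and diabetes.
#'
#' @return a [rule_config()] object.
#' @export
default_rule_config <- function() {
  path <- system.file("extdata", "default_rules.yaml", package = "certaudit")
  if (path == "") { # not installed; during development
    path <- file.path("inst", "extdata", "default_rules.yaml")
  }
  read_rule_config(path)
}

# Map a vector of raw condition texts to categories (NA when unmapped).
condition_category <- function(text, config) {
  unname(config$categories[normalize_text(text)])
}
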