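# Profile, rules, model and prior configuration I/O, plus run manifests.

.KEY_RE <- "^(Fuc[0-9]+)?(NeuAc[0-9]+)?(Hex[0-9]+)?(HexNAc[0-9]+)?(Glc[0-9]+)?$"

validate_composition_key <- function(keys) {
  bad <- which(!grepl(.KEY_RE, keys) | keys == "")
  bad
}

#' Write / read a glycan profile as TSV
#'
#' Schema: header `composition<TAB>abundance_pct<TAB>sem_pct`, one row per
#' composition key, keys sorted; abundances printed with full precision so
#' write-then-read is an identity.
#'
#' @param profile a [glycan_profile()].
#' @param path file path.
#' @return `write_profile` returns `path` invisibly; `read_profile` a
#'   [glycan_profile()].
#' @export
write_profile <- function(profile, path) {
  df <- data.frame(composition = profile$composition,
                   abundance_pct = sprintf("%.17g", profile$abundance_pct),
                   sem_pct = ifelse(is.na(profile$sem_pct), "NA",
                                    sprintf("%.17g", profile$sem_pct)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile
#' @param check_total error when the abundances are declared pre-filter
#'   (`pre_filter = TRUE`) and do not sum to 100 within `tolerance`.
#' @param pre_filter whether the file claims unfiltered abundances.
#' @param tolerance allowed deviation of the pre-filter total from 100.
#' @export
read_profile <- function(path, pre_filter = FALSE, tolerance = 1e-6,
                         check_total = pre_filter) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("composition", "abundance_pct")
  if (!all(need %in% names(df)))
    stop("profile file ", path, " lacks column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  bad <- validate_composition_key(df$composition)
  if (length(bad))
    stop("bad composition key in ", path, " row ", bad[1L], ": '",
         df$composition[bad[1L]], "'")
  if (any(df$abundance_pct < 0))
    stop("negative abundance in ", path, " row ",
         which(df$abundance_pct < 0)[1L], " column abundance_pct")
  if (check_total && abs(sum(df$abundance_pct) - 100) > tolerance)
    stop("pre-filter abundances in ", path, " sum to ",
         sum(df$abundance_pct), ", not 100")
  sem <- if ("sem_pct" %in% names(df)) df$sem_pct else NA_real_
  glycan_profile(df$composition, df$abundance_pct, sem)
}

# ---- rules ---------------------------------------------------------------

#' Write / read an enzyme rule configuration (YAML)
#'
#' One record per rule (enzyme, action, added residue, target pattern,
#' guards, scale-factor id) plus the scale-factor table.  The shipped
#' default file `system.file("extdata", "rules_default.yaml", package =
#' "golgisim")` reproduces [default_mammalian_rules()] exactly.
#'
#' @param ruleset `list(rules, scales)`.
#' @param path file path.
#' @return `write_rules_config` returns `path` invisibly;
#'   `read_rules_config` the rule set.
#' @export
write_rules_config <- function(ruleset, path) {
  rules <- lapply(ruleset$rules, function(r) {
    out <- list(name = r$name, enzyme = r$enzyme, action = r$action)
    if (!is.null(r$sugar)) { out$sugar <- r$sugar; out$linkage <- r$linkage }
    if (length(r$target)) out$target <- r$target
    if (length(r$guards)) out$guards <- r$guards
    if (!is.null(r$scale_factor_id)) out$scale_factor_id <- r$scale_factor_id
    out
  })
  sc <- ruleset$scales
  scales <- lapply(seq_len(nrow(sc)), function(i) {
    e <- as.list(sc[i, ])
    e[!vapply(e, function(v) is.atomic(v) && is.na(v), logical(1))]
  })
  writeLines(yaml::as.yaml(list(rules = rules, scale_factors = scales),
                           precision = 15L), path)
  invisible(path)
}

#' @rdname write_rules_config
#' @export
read_rules_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  as_int_fields <- c("man_eq", "man_min", "man_max", "antennae_min",
                     "antennae_max", "glc_eq")
  rules <- lapply(cfg$rules, function(r) {
    guards <- r$guards
    for (f in intersect(names(guards), as_int_fields))
      guards[[f]] <- as.integer(guards[[f]])
    target <- r$target
    if (!is.null(target$linkage))
      target$linkage <- as.character(unlist(target$linkage))
    enzyme_rule(r$name, r$enzyme, r$action, sugar = r$sugar,
                linkage = r$linkage,
                target = if (is.null(target)) list() else target,
                guards = if (is.null(guards)) list() else guards,
                scale_factor_id = r$scale_factor_id)
  })
  sf <- cfg$scale_factors
  pick <- function(f, default) vapply(sf, function(e)
    if (is.null(e[[f]])) default else e[[f]], default)
  scales <- scale_factor_table(
    id = pick("id", ""), enzyme = pick("enzyme", ""),
    multiplier = pick("multiplier", 0),
    man_eq = as.integer(pick("man_eq", NA_integer_)),
    antennae_min = as.integer(pick("antennae_min", NA_integer_)),
    arm = pick("arm", NA_character_))
  list(rules = rules, scales = scales)
}

#' Shipped default rules file
#' @return Path to `rules_default.yaml` inside the installed package.
#' @export
default_rules_path <- function() {
  system.file("extdata", "rules_default.yaml", package = "golgisim",
              mustWork = TRUE)
}

# ---- model ---------------------------------------------------------------

#' Write / read a Golgi model configuration (YAML)
#'
#' Stores cisterna count, residence times, the enzyme-by-cisterna rate
#' table and the ER-input distribution.
#'
#' @param model a [golgi_model()].
#' @param path file path.
#' @return `write_model_config` returns `path` invisibly;
#'   `read_model_config` a [golgi_model()].
#' @export
write_model_config <- function(model, path) {
  cfg <- list(
    cisternae = ncol(model$rates),
    residence_time = as.numeric(model$residence_time),
    input_distribution = as.list(model$input_distribution),
    rates = setNames(lapply(rownames(model$rates),
                            function(e) as.numeric(model$rates[e, ])),
                     rownames(model$rates)))
  writeLines(yaml::as.yaml(cfg, precision = 15L), path)
  invisible(path)
}

#' @rdname write_model_config
#' @export
read_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  rates <- do.call(rbind, cfg$rates)
  rownames(rates) <- names(cfg$rates)
  if (ncol(rates) != cfg$cisternae)
    stop("model config ", path, ": rates rows have ", ncol(rates),
         " cisternae but 'cisternae' is ", cfg$cisternae)
  golgi_model(rates, residence_time = unlist(cfg$residence_time),
              input_distribution = unlist(cfg$input_distribution))
}

# ---- priors --------------------------------------------------------------

#' Write / read a prior specification (TSV)
#'
#' Columns: param, dist (lnorm/exp), p1, p2.
#'
#' @param priors a [prior_spec()].
#' @param path file path.
#' @return `write_priors_config` returns `path` invisibly;
#'   `read_priors_config` a [prior_spec()].
#' @export
write_priors_config <- function(priors, path) {
  write.table(as.data.frame(priors), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_priors_config
#' @export
read_priors_config <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  prior_spec(df$param, df$dist, df$p1, df$p2)
}

# ---- cross-validation ----------------------------------------------------

#' Cross-validate model, rules and prior configurations
#'
#' Checks that every prior names an existing (enzyme, cisterna) rate
#' entry, that every rule's enzyme has a rate row, and that cisterna
#' indices are contiguous from 1.  Rates for an enzyme with no rule yield
#' a warning (permissive), everything else an error naming the offending
#' key.
#'
#' @param model a [golgi_model()].
#' @param ruleset `list(rules, scales)`.
#' @param priors optional [prior_spec()].
#' @return Invisibly `TRUE`; errors/warnings otherwise.
#' @export
validate_config <- function(model, ruleset, priors = NULL) {
  enz_rules <- rule_enzymes(ruleset$rules)
  enz_model <- rownames(model$rates)
  missing <- setdiff(enz_rules, enz_model)
  if (length(missing))
    stop("rules reference enzyme(s) with no rates: ",
         paste(missing, collapse = ", "))
  extra <- setdiff(enz_model, enz_rules)
  if (length(extra))
    warning("rates given for enzyme(s) with no rule: ",
            paste(extra, collapse = ", "))
  if (!is.null(priors)) {
    enz <- sub("\\.c[0-9]+$", "", priors$param)
    cis <- suppressWarnings(as.integer(sub("^.*\\.c", "", priors$param)))
    bad <- is.na(cis) | !(enz %in% enz_model) | cis < 1L |
      cis > n_cisternae(model)
    if (any(bad))
      stop("prior parameter(s) do not name an (enzyme, cisterna) of the ",
           "model: ", paste(priors$param[bad], collapse = ", "))
  }
  invisible(TRUE)
}

# ---- run manifest --------------------------------------------------------

#' Write a run manifest
#'
#' Records the package version, seed, input-configuration hashes and
#' output file list for one run as JSON; identical inputs yield an
#' identical manifest.
#'
#' @param path manifest path.
#' @param seed master seed of the run.
#' @param inputs named character vector of input file paths (hashed).
#' @param outputs character vector of output file paths.
#' @param stage label of the pipeline stage.
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(path, seed, inputs = character(),
                           outputs = character(), stage = "run") {
  hashes <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  man <- list(package = "golgisim",
              version = as.character(utils::packageVersion("golgisim")),
              stage = stage, seed = seed, input_md5 = hashes,
              outputs = as.list(outputs))
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(man)
}
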