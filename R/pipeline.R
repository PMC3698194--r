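#' Default analysis configuration
#'
#' The model roster reproducing the package's reference analysis: the FMR
#' model (`fmr ~ manipulation + log10 body mass`), the WL model
#' (`log10 WL ~ manipulation + log10 body mass`), the wasps-only FMR model
#' (prey-feeders, with group-specific residual variances), and the WL-FMR
#' covariation model, plus the allometric fit and the Mk1 ancestral
#' reconstruction of the manipulation character.  Users can add or edit
#' models without code changes, either on the returned list or in a YAML
#' file (see [read_config()]; the bundled copy is
#' `system.file("extdata", "paper.yaml", package = "hymeflight")`).
#'
#' @return a list of class `"hymeflight_config"`.
#' @export
default_config <- function() {
  structure(list(
    lambda = "ML",
    lift = NULL,        # list(a = , b = ) lift-regression coefficients
    models = list(
      list(name = "fmr_model", response = "fmr", log10_response = FALSE,
           predictors = c("manipulation", "body_mass_g"),
           log10_predictors = "body_mass_g", subset = NULL,
           var_group = NULL),
      list(name = "wl_model", response = "wing_loading_g_cm2",
           log10_response = TRUE,
           predictors = c("manipulation", "body_mass_g"),
           log10_predictors = "body_mass_g", subset = NULL,
           var_group = NULL),
      list(name = "wasp_fmr_model", response = "fmr",
           log10_response = FALSE,
           predictors = c("manipulation", "body_mass_g"),
           log10_predictors = "body_mass_g", subset = "diet == 'prey'",
           var_group = "manipulation"),
      list(name = "covariation_model", response = "wing_loading_g_cm2",
           log10_response = TRUE, predictors = c("fmr", "body_mass_g"),
           log10_predictors = "body_mass_g", subset = NULL,
           var_group = NULL))),
    class = "hymeflight_config")
}

#' Read an analysis configuration from YAML
#'
#' Fields present in the file override [default_config()]; models given in
#' the file replace the default roster.
#'
#' @param path YAML file path.
#' @return a list of class `"hymeflight_config"`.
#' @export
read_config <- function(path) {
  cfg <- default_config()
  y <- yaml::read_yaml(path)
  if (!is.null(y$lambda)) cfg$lambda <- y$lambda
  if (!is.null(y$lift)) cfg$lift <- y$lift
  if (!is.null(y$models)) {
    cfg$models <- lapply(y$models, function(m) {
      list(name = m$name, response = m$response,
           log10_response = isTRUE(m$log10_response),
           predictors = unlist(m$predictors),
           log10_predictors = unlist(m$log10_predictors),
           subset = m$subset, var_group = m$var_group)
    })
  }
  cfg
}

model_formula <- function(m) {
  wrap <- function(v) ifelse(v %in% m$log10_predictors,
                             paste0("log10(", v, ")"), v)
  resp <- if (m$log10_response) paste0("log10(", m$response, ")") else
    m$response
  as.formula(paste(resp, "~", paste(wrap(m$predictors), collapse = " + ")))
}

#' Run the full comparative analysis
#'
#' Executes the whole pipeline on a trait table and a phylogeny:
#' validation, derivation of FMR and wing loading from raw measurements
#' where absent, load-capacity prediction (when lift coefficients are
#' configured), every PGLS model in the configuration, the allometric fit
#' of wing loading on body mass, and the Mk1 ancestral reconstruction and
#' parsimony origin count of the manipulation character.  Models with too
#' few species are skipped with a logged reason; everything else proceeds.
#' Re-running with identical inputs yields an identical report.
#'
#' @param traits trait table: a data.frame or a CSV path.
#' @param tree phylogeny: a `"phylo"` object or a Newick path.  A tree
#'   without branch lengths gets Grafen lengths, with a log note.
#' @param config a configuration list from [default_config()] or
#'   [read_config()].
#' @param out_dir optional directory; when given, writes `table2.tsv`,
#'   `descriptive.tsv`, `loads.tsv`, `ancestry.tsv` and `run.log`.
#' @return an object of class `"hymeflight_report"`.
#' @examples
#' rep <- run_full_analysis(hymeflight_table1(), hymeflight_tree())
#' print(rep)
#' @export
run_full_analysis <- function(traits, tree, config = default_config(),
                              out_dir = NULL) {
  log_lines <- character()
  note <- function(...) {
    line <- paste0(...)
    message(line)
    log_lines <<- c(log_lines, line)
  }

  prov <- list(package_version = as.character(packageVersion("hymeflight")))
  if (is.character(traits)) {
    prov$traits_md5 <- unname(tools::md5sum(traits))
    traits <- read_traits(traits)
  } else {
    flags <- validate_traits(traits)
    if (nrow(flags)) note("trait flags: ", nrow(flags), " inconsistencies")
  }
  if (is.character(tree)) {
    prov$tree_md5 <- unname(tools::md5sum(tree))
    tree <- read_phylogeny(tree)
  }
  validate_phylogeny(tree)
  if (!has_branch_lengths(tree)) {
    note("tree has no branch lengths; assigning Grafen lengths")
    tree <- grafen_lengths(tree)
  }
  unmatched <- setdiff(trimws(traits$tree_name), tree$tip.label)
  if (length(unmatched))
    stop("species not found among tree tips: ",
         paste(unmatched, collapse = ", "), call. = FALSE)
  traits$tree_name <- trimws(traits$tree_name)
  traits <- derive_traits(traits)
  note("input: ", nrow(traits), " species, tree with ",
       ape::Ntip(tree), " tips")

  # descriptive statistics per manipulation group
  descriptive <- do.call(rbind, lapply(
    c("body_mass_g", "fmr", "wing_loading_g_cm2"), function(v) {
      gs <- group_stats(traits[[v]], traits$manipulation)
      cbind(variable = v, gs)
    }))
  note("descriptive: ranges Mb [", min(traits$body_mass_g), ", ",
       max(traits$body_mass_g), "] g")

  # load capacity (needs externally supplied lift coefficients)
  loads <- NULL
  if (!is.null(config$lift)) {
    lp <- lift_params(config$lift$a, config$lift$b)
    ok <- !is.na(traits$fmr)
    loads <- cbind(traits[ok, c("species", "tree_name", "manipulation")],
                   load_capacity(traits$body_mass_g[ok], traits$fmr[ok], lp))
    note("loads: mean Load_max = ", round(mean(loads$Load_max), 4),
         " g over ", nrow(loads), " species")
  } else {
    note("loads: skipped (no lift-regression coefficients configured)")
  }

  # PGLS model roster
  models <- list()
  for (m in config$models) {
    df <- traits
    if (!is.null(m$subset))
      df <- df[eval(parse(text = m$subset), df), , drop = FALSE]
    fit <- tryCatch(
      pgls(model_formula(m), df, tree, lambda = config$lambda,
           var_group = m$var_group),
      error = function(e) e)
    if (inherits(fit, "error")) {
      note("model ", m$name, ": skipped (", conditionMessage(fit), ")")
    } else {
      models[[m$name]] <- fit
      note("model ", m$name, ": n = ", fit$n, ", lambda = ",
           round(fit$lambda, 3), ", coef[2] = ",
           round(fit$coefficients[2], 4))
    }
  }

  # allometric scaling of wing loading with body mass
  allometry <- tryCatch(
    allometry_fit(traits$body_mass_g, traits$wing_loading_g_cm2),
    error = function(e) { note("allometry: skipped (",
                               conditionMessage(e), ")"); NULL })
  if (!is.null(allometry))
    note("allometry: exponent = ", round(allometry$exponent, 3),
         ", r2 = ", round(allometry$r2, 3), ", n = ", allometry$n)

  # ancestral reconstruction of the manipulation character
  states <- setNames(traits$manipulation, traits$tree_name)
  ancestry <- NULL; origins <- NULL
  if (!any(is.na(states))) {
    ancestry <- asr_mk1(tree, states)
    root <- ape::Ntip(tree) + 1L
    rootcall <- ancestry$nodes$call[ancestry$nodes$node == root]
    origins <- count_origins(tree, states)
    note("ancestry: q = ", signif(ancestry$q, 4), ", root call = ",
         rootcall, ", parsimony score = ", origins$score, " (",
         origins$gains, " gains, ", origins$losses, " losses)")
  } else {
    note("ancestry: skipped (missing manipulation states)")
  }

  prov$species_per_model <- lapply(models, `[[`, "species")
  out <- list(descriptive = descriptive, loads = loads, models = models,
              allometry = allometry, ancestry = ancestry, origins = origins,
              provenance = prov, log = log_lines, traits = traits,
              tree = tree)
  class(out) <- "hymeflight_report"
  if (!is.null(out_dir)) write_report(out, out_dir)
  out
}

model_table <- function(models) {
  do.call(rbind, lapply(names(models), function(nm) {
    f <- models[[nm]]
    data.frame(model = nm, predictor = names(f$coefficients),
               estimate = unname(f$coefficients), se = unname(f$se),
               t = unname(f$tstat), p = unname(f$pval),
               lambda = f$lambda, n = f$n, logLik = f$logLik,
               lr_lambda_p = f$lr_lambda$p_value,
               stringsAsFactors = FALSE)
  }))
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(x, f) utils::write.table(
    x, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  if (length(report$models)) tsv(model_table(report$models), "table2.tsv")
  tsv(report$descriptive, "descriptive.tsv")
  if (!is.null(report$loads)) tsv(report$loads, "loads.tsv")
  if (!is.null(report$ancestry)) {
    ntip <- ape::Ntip(report$tree)
    sets <- clade_tip_sets(report$tree)
    anc <- report$ancestry$nodes
    anc$tip_set <- vapply(anc$node, function(v)
      paste(sort(report$tree$tip.label[sets[[v - ntip]]]), collapse = "|"),
      character(1))
    tsv(anc, "ancestry.tsv")
  }
  writeLines(report$log, file.path(out_dir, "run.log"))
  invisible(out_dir)
}

#' @export
print.hymeflight_report <- function(x, digits = 3, ...) {
  cat("hymeflight analysis report\n")
  cat("Species:", nrow(x$traits), " Tree tips:", ape::Ntip(x$tree), "\n\n")
  if (length(x$models)) {
    cat("PGLS models:\n")
    tab <- model_table(x$models)
    tab[] <- lapply(tab, function(v) if (is.numeric(v)) signif(v, digits)
                    else v)
    print(tab, row.names = FALSE)
  }
  if (!is.null(x$allometry)) { cat("\n"); print(x$allometry) }
  if (!is.null(x$origins))
    cat("\nManipulation ability: parsimony score ", x$origins$score, " (",
        x$origins$gains, " gains, ", x$origins$losses,
        " losses); root state ", x$origins$root_state, "\n", sep = "")
  invisible(x)
}
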