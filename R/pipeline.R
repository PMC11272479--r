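#' Batch rectification extraction from a manifest
#'
#' Runs the full per-socket pipeline — coarse + ICP alignment, deviation
#' mapping, profile extraction — for every row of a manifest, collecting the
#' results into a cohort table. A failing row is flagged in the `status`
#' column and does not stop the remaining rows.
#'
#' @param manifest data frame (or CSV path) with columns `socket_id`, `limb`,
#'   `socket`, `landmarks_limb`, `landmarks_socket`, `masks`, `anterior`
#'   (JSON array of 0-based limb vertex indices), and optionally `design`
#'   and `override` (transform JSON applied after ICP).
#' @param out_csv optional path; the cohort table is written there with a
#'   provenance header.
#' @param seed seed recorded in the output header (the extraction itself is
#'   deterministic).
#' @return tibble: one row per manifest row with the eight design variables,
#'   alignment RMS diagnostics, `status` ("ok" or the error message).
#' @export
run_extract <- function(manifest, out_csv = NULL, seed = NA_integer_) {
  if (is.character(manifest)) {
    manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE,
                                comment.char = "#")
  }
  need <- c("socket_id", "limb", "socket", "landmarks_limb",
            "landmarks_socket", "masks", "anterior")
  miss <- setdiff(need, names(manifest))
  if (length(miss)) {
    stop("malformed manifest: missing column(s) ", paste(miss, collapse = ", "))
  }
  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    res <- tryCatch({
      limb <- read_mesh(row$limb)
      socket <- read_mesh(row$socket)
      lm_l <- read_landmarks(row$landmarks_limb)
      lm_s <- read_landmarks(row$landmarks_socket)
      masks <- read_masks(row$masks, mesh = limb)
      anterior <- as.integer(jsonlite::read_json(row$anterior,
                                                 simplifyVector = TRUE)) + 1L
      override <- NULL
      if ("override" %in% names(row) && !is.na(row$override) &&
          nzchar(row$override)) {
        override <- read_transform(row$override)
      }
      al <- align_pair(limb, socket, lm_l, lm_s, anterior, override = override)
      sock_al <- apply_transform(socket, al$transform)
      design <- if ("design" %in% names(row)) row$design else NA_character_
      prof <- extract_profile(limb, sock_al, lm_l, masks,
                              socket_id = row$socket_id, design = design)
      out <- profile_row(prof)
      out$coarse_rms <- al$coarse$rms
      out$icp_rms <- al$icp$rms
      out$icp_iterations <- al$icp$iterations
      out$icp_converged <- al$icp$converged
      out$status <- "ok"
      out
    }, error = function(e) {
      tibble::tibble(socket_id = row$socket_id, design = NA_character_,
                     PT = NA_real_, FH = NA_real_, MP = NA_real_,
                     LP = NA_real_, TC = NA_real_, DE = NA_real_,
                     LMC = NA_real_, VR = NA_real_,
                     coarse_rms = NA_real_, icp_rms = NA_real_,
                     icp_iterations = NA_integer_, icp_converged = NA,
                     status = conditionMessage(e))
    })
    res
  })
  out <- dplyr::bind_rows(rows)
  if (!is.null(out_csv)) {
    write_table_with_header(out, out_csv, seed = seed)
  }
  out
}

#' Cohort-level analysis report bundle
#'
#' Emits the full set of cohort analyses to a directory: a stratified
#' demographic summary, per-design rectification comparison (Mann-Whitney
#' with Bonferroni), the Spearman correlation matrices, the KDE category
#' table (cuts and exemplars per design variable), pairwise naive-Bayes
#' probability panels, and most-probable template designs for high and low
#' volume reduction (rendered onto a limb mesh as a PLY deviation map when
#' one is supplied). Statistics whose sample-size requirements are not met
#' are reported as missing rather than failing the run.
#'
#' @param cohort a design cohort (or cohort CSV path).
#' @param out_dir output directory, created if needed.
#' @param config list: `seed`, `merge_sc`, `bonferroni_m`,
#'   `template_choices` (categories of VR to expand into templates), and
#'   optionally `limb`, `masks`, `landmarks` (a `synthetic_limb` or paths)
#'   for template rendering.
#' @return invisible list of the written file paths.
#' @export
run_analysis <- function(cohort, out_dir, config = list()) {
  defaults <- list(seed = NA_integer_, merge_sc = TRUE, bonferroni_m = 8,
                   template_choices = c("high", "low"))
  unknown <- setdiff(names(config), c(names(defaults), "limb", "masks",
                                      "landmarks"))
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "))
  config <- utils::modifyList(defaults, config)
  if (is.character(cohort)) {
    cohort <- utils::read.csv(cohort, stringsAsFactors = FALSE,
                              comment.char = "#")
  }
  cohort <- as_design_cohort(cohort)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  emit <- function(x, name) {
    p <- file.path(out_dir, name)
    write_table_with_header(x, p, seed = config$seed, config = config)
    written <<- c(written, p)
  }

  summ <- dplyr::bind_rows(cohort_summary(cohort, "overall"),
                           if ("design" %in% names(cohort))
                             cohort_summary(cohort, "design"))
  emit(summ, "summary.csv")

  if ("design" %in% names(cohort) &&
      all(c("PTB", "TSB") %in% two_group_design(cohort$design))) {
    cmp <- tryCatch(compare_designs(cohort, merge_sc = config$merge_sc,
                                    m = config$bonferroni_m),
                    error = function(e) NULL)
    if (!is.null(cmp)) emit(cmp, "design_comparison.csv")
  }

  sp <- tryCatch(spearman_matrix(cohort), error = function(e) NULL)
  if (is.null(sp)) {
    v <- design_variables()
    sp <- list(rho = matrix(NA_real_, 8, 8, dimnames = list(v, v)),
               p = matrix(NA_real_, 8, 8, dimnames = list(v, v)))
  }
  emit(as.data.frame(cbind(variable = rownames(sp$rho), as.data.frame(sp$rho))),
       "spearman_rho.csv")
  emit(as.data.frame(cbind(variable = rownames(sp$p), as.data.frame(sp$p))),
       "spearman_p.csv")

  cuts <- tryCatch(fit_all_categories(cohort), error = function(e) NULL)
  if (is.null(cuts)) {
    cat_tab <- tibble::tibble(variable = design_variables(),
                              cut_low = NA_real_, cut_high = NA_real_,
                              exemplar_low = NA_real_, exemplar_mid = NA_real_,
                              exemplar_high = NA_real_)
  } else {
    cat_tab <- dplyr::bind_rows(lapply(names(cuts), function(v) {
      ct <- cuts[[v]]
      tibble::tibble(variable = v, cut_low = ct$cut_low, cut_high = ct$cut_high,
                     exemplar_low = ct$exemplar_low,
                     exemplar_mid = ct$exemplar_mid,
                     exemplar_high = ct$exemplar_high)
    }))
  }
  emit(cat_tab, "categories.csv")

  if (!is.null(cuts)) {
    vars <- design_variables()
    panels <- list()
    for (target in vars) {
      for (cond in setdiff(vars, target)) {
        nb <- tryCatch(suppressWarnings(
          fit_conditional_nb(cohort, target, cond, cuts = cuts[[target]])),
          error = function(e) NULL)
        if (is.null(nb)) next
        for (cat_ in c("low", "mid", "high")) {
          x <- switch(cat_, low = cuts[[cond]]$exemplar_low,
                      mid = cuts[[cond]]$exemplar_mid,
                      high = cuts[[cond]]$exemplar_high)
          pr <- conditional_probabilities(nb, x)[1, ]
          panels[[length(panels) + 1]] <- tibble::tibble(
            target = target, conditioning = cond,
            conditioning_category = cat_, conditioning_value = x,
            p_low = pr[["low"]], p_mid = pr[["mid"]], p_high = pr[["high"]])
        }
      }
    }
    emit(dplyr::bind_rows(panels), "pairwise_probabilities.csv")

    for (cat_ in config$template_choices) {
      tpl <- tryCatch(generate_template(cohort, cuts, "VR", cat_),
                      error = function(e) NULL)
      if (is.null(tpl)) next
      p <- file.path(out_dir, sprintf("template_VR_%s.json", cat_))
      jsonlite::write_json(list(tool = "socketmap",
                                version = as.character(pkg_version()),
                                seed = config$seed,
                                config_hash = config_hash(config),
                                chosen = attr(tpl, "chosen"),
                                template = tpl),
                           p, auto_unbox = TRUE, digits = NA)
      written <- c(written, p)
      if (!is.null(config$limb)) {
        limb <- config$limb
        if (inherits(limb, "synthetic_limb")) {
          map <- render_template_map(tpl, limb$mesh, limb$masks, limb$landmarks)
          mp <- file.path(out_dir, sprintf("template_VR_%s_map.ply", cat_))
          write_mesh(limb$mesh, mp, format = "ply", scalar = unclass(map))
          written <- c(written, mp)
        }
      }
    }
  }
  invisible(written)
}

pkg_version <- function() {
  tryCatch(utils::packageVersion("socketmap"), error = function(e) "0.0.0")
}

# small deterministic hash of the config list for output provenance
config_hash <- function(config) {
  s <- paste(utils::capture.output(utils::str(config)), collapse = "\n")
  b <- utf8ToInt(s)
  h <- 5381
  for (x in b) h <- (h * 33 + x) %% 2^31
  sprintf("%08x", h)
}

write_table_with_header <- function(x, path, seed = NA_integer_, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# socketmap %s | seed=%s | config=%s",
                     as.character(pkg_version()),
                     ifelse(is.na(seed), "NA", seed),
                     if (is.null(config)) "none" else config_hash(config)), con)
  utils::write.csv(x, con, row.names = FALSE)
  invisible(path)
}

#' Write generator outputs for one synthetic limb/socket pair
#'
#' Emits limb and socket meshes (STL), landmark and mask JSON, the anterior
#' ICP mask, and the ground truth JSON into a directory — the fixture layout
#' [run_extract()] manifests point at.
#'
#' @param limb a `synthetic_limb`.
#' @param socket result of [generate_socket()].
#' @param dir output directory.
#' @return named list of the written paths.
#' @export
write_pair_fixture <- function(limb, socket, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    limb = file.path(dir, "limb.stl"),
    socket = file.path(dir, "socket.stl"),
    landmarks_limb = file.path(dir, "landmarks_limb.json"),
    landmarks_socket = file.path(dir, "landmarks_socket.json"),
    masks = file.path(dir, "masks.json"),
    anterior = file.path(dir, "anterior.json"),
    truth = file.path(dir, "truth.json"))
  write_mesh(limb$mesh, paths$limb, format = "stl")
  write_mesh(socket$mesh, paths$socket, format = "stl")
  write_landmarks(limb$landmarks, paths$landmarks_limb)
  # socket landmarks: limb landmarks carried through the socket's pose
  lm_s <- limb$landmarks
  if (!is.null(socket$truth$pose)) {
    lm_s <- landmark_set(rt_apply_points(socket$truth$pose, limb$landmarks))
  }
  write_landmarks(lm_s, paths$landmarks_socket)
  write_masks(limb$masks, paths$masks)
  jsonlite::write_json(as.integer(limb$anterior) - 1L, paths$anterior)
  tr <- socket$truth
  jsonlite::write_json(list(profile = unclass(tr$profile),
                            noise_sd = tr$noise_sd, seed = tr$seed),
                       paths$truth, auto_unbox = TRUE, digits = NA,
                       null = "null")
  paths
}
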