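# Hierarchical prior structure. Married women: world -> region ->
# subregion -> country. Unmarried women: subregions are additionally
# clustered into two sexual-activity groups (group 0: <= 2% of unmarried
# women of reproductive age report sexual activity in the past 28 days),
# giving world -> activity group -> region -> subregion -> country, with
# geographic subregions kept intact inside each group. Shrinkage is by
# normal child-given-parent terms on unconstrained scales (logit for
# asymptotes, log for rates, identity for midpoints and the unmet-need
# intercept).

#' Default hierarchical prior settings
#'
#' Root (world) means and standard deviations for each transition
#' parameter on its unconstrained scale, and half-normal scales for the
#' level standard deviations. Midpoint priors are wide (decades); rate
#' priors centre on a transition spanning roughly 30-60 years.
#'
#' @return list with `root_mean`, `root_sd` (named over parameters) and
#'   `hn_scale`, a matrix levels x parameters of half-normal scales.
#' @export
default_hierarchy_priors <- function() {
  root_mean <- c(la_any = 0, lr_any = log(0.08), m_any = 2005,
                 la_ratio = logit(0.8), lr_ratio = log(0.08),
                 m_ratio = 2000, u_int = logit(0.15))
  root_sd <- c(la_any = 1, lr_any = 0.5, m_any = 20,
               la_ratio = 1, lr_ratio = 0.5, m_ratio = 20, u_int = 1)
  lv <- c("group", "region", "subregion", "country")
  hn <- rbind(
    group     = c(0.5, 0.3, 10, 0.5, 0.3, 10, 0.5),
    region    = c(0.5, 0.3, 10, 0.5, 0.3, 10, 0.5),
    subregion = c(0.4, 0.25, 8, 0.4, 0.25, 8, 0.4),
    country   = c(0.4, 0.25, 6, 0.4, 0.25, 6, 0.4)
  )
  colnames(hn) <- PARAM_NAMES
  list(root_mean = root_mean, root_sd = root_sd, hn_scale = hn)
}

#' Assign a sexual-activity group
#'
#' Subregions (and thus countries) are clustered by the proportion of
#' unmarried women of reproductive age reporting sexual activity in the
#' past 28 days: at or below the threshold (default 2%) is group 0, above
#' it group 1. When no measurement is available the value must be resolved
#' externally and passed as `fallback`; it is never guessed.
#'
#' @param pct_active_28d percentage in \[0, 100\], or `NA`.
#' @param threshold inclusive boundary, percent (default 2).
#' @param fallback group value (0 or 1) from metadata, used when the
#'   measurement is missing.
#' @return integer 0 or 1.
#' @export
assign_activity_group <- function(pct_active_28d, threshold = 2,
                                  fallback = NA) {
  if (is.na(pct_active_28d)) {
    if (is.na(fallback)) {
      stop("no sexual-activity measurement and no metadata fallback",
           call. = FALSE)
    }
    return(as.integer(fallback))
  }
  if (pct_active_28d < 0 || pct_active_28d > 100) {
    stop("pct_active_28d must lie in [0, 100]", call. = FALSE)
  }
  if (pct_active_28d <= threshold) 0L else 1L
}

#' Build the shrinkage tree for one marital group
#'
#' @param meta country metadata data.frame with columns `country_code`,
#'   `subregion`, `region`, and (for unmarried) `activity_group`.
#' @param marital_group `"married"` or `"unmarried"`.
#' @param priors output of [default_hierarchy_priors()].
#' @return object of class `hierarchy_tree`: node table (`id`, `parent`,
#'   `level`), country-to-leaf map, level names, and the priors.
#' @export
build_hierarchy <- function(meta, marital_group = c("married", "unmarried"),
                            priors = default_hierarchy_priors()) {
  marital_group <- match.arg(marital_group)
  if (anyDuplicated(meta$country_code)) {
    stop("country listed more than once in metadata: ",
         paste(unique(meta$country_code[duplicated(meta$country_code)]),
               collapse = ", "), call. = FALSE)
  }
  if (any(is.na(meta$subregion)) || any(is.na(meta$region))) {
    stop("every country needs a subregion and region", call. = FALSE)
  }

  nodes <- data.frame(id = "world", parent = NA_character_,
                      level = "world", stringsAsFactors = FALSE)
  add_node <- function(id, parent, level) {
    if (!id %in% nodes$id) {
      nodes <<- rbind(nodes, data.frame(id = id, parent = parent,
                                        level = level))
    }
  }

  if (marital_group == "married") {
    levels <- c("world", "region", "subregion", "country")
    for (i in seq_len(nrow(meta))) {
      r <- paste0("r:", meta$region[i])
      s <- paste0("s:", meta$subregion[i])
      add_node(r, "world", "region")
      add_node(s, r, "subregion")
      add_node(paste0("c:", meta$country_code[i]), s, "country")
    }
  } else {
    if (is.null(meta$activity_group) || any(is.na(meta$activity_group))) {
      stop("activity_group must be resolved for every country", call. = FALSE)
    }
    # subregions inherit the group of their countries; a subregion split
    # across groups is a metadata error
    grp <- tapply(meta$activity_group, meta$subregion,
                  function(g) {
                    u <- unique(g)
                    if (length(u) > 1) {
                      stop("subregion spans both activity groups",
                           call. = FALSE)
                    }
                    u
                  })
    levels <- c("world", "group", "region", "subregion", "country")
    add_node("g:0", "world", "group")
    add_node("g:1", "world", "group")
    for (i in seq_len(nrow(meta))) {
      g <- grp[[meta$subregion[i]]]
      gn <- paste0("g:", g)
      r <- paste0("g", g, "/r:", meta$region[i])
      s <- paste0("g", g, "/s:", meta$subregion[i])
      add_node(r, gn, "region")
      add_node(s, r, "subregion")
      add_node(paste0("c:", meta$country_code[i]), s, "country")
    }
  }

  country_ids <- paste0("c:", meta$country_code)
  structure(list(marital_group = marital_group, levels = levels,
                 nodes = nodes, countries = meta$country_code,
                 country_parent = setNames(
                   nodes$parent[match(country_ids, nodes$id)],
                   meta$country_code),
                 priors = priors),
            class = "hierarchy_tree")
}

# internal (non-leaf) nodes in update order, root last
internal_nodes <- function(tree) {
  tree$nodes[tree$nodes$level != "country", , drop = FALSE]
}

#' Hierarchical prior log-density
#'
#' Sum of normal shrinkage terms child-given-parent at every level of the
#' tree, half-normal hyperpriors on the level standard deviations, and the
#' root-mean prior.
#'
#' @param theta matrix countries x 7 of country parameters on the
#'   unconstrained scales (rows named by country code, columns by
#'   parameter).
#' @param node_means matrix internal-nodes x 7 (rows named by node id,
#'   including `"world"`).
#' @param level_sds matrix levels x 7 for the non-root levels present in
#'   the tree (rows named by level).
#' @param tree a [build_hierarchy()] object.
#' @return scalar log-density.
#' @export
prior_logdensity <- function(theta, node_means, level_sds, tree) {
  pr <- tree$priors
  ld <- sum(stats::dnorm(node_means["world", ], pr$root_mean, pr$root_sd,
                         log = TRUE))
  non_root <- setdiff(tree$levels, "world")
  for (lv in non_root) {
    ld <- ld + sum(dhalfnorm_log(level_sds[lv, ], pr$hn_scale[lv, ]))
  }
  nd <- tree$nodes
  for (i in which(!is.na(nd$parent))) {
    lv <- nd$level[i]
    val <- if (lv == "country") {
      theta[sub("^c:", "", nd$id[i]), ]
    } else {
      node_means[nd$id[i], ]
    }
    parent <- node_means[nd$parent[i], ]
    ld <- ld + sum(stats::dnorm(val, parent, level_sds[lv, ], log = TRUE))
  }
  ld
}
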