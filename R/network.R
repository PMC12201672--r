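# Population-level constants: synaptic group multipliers and plasticity
# rates by (presynaptic class, postsynaptic class).  Classes are EB
# (engram backbone), SF (sparsely firing excitatory) and INH.
.group_class <- function(group) {
  ifelse(grepl("^EB", group), "EB", ifelse(grepl("^SF", group), "SF", "INH"))
}

.multiplier_table <- function(inh_to_eb = 0.5, inh_to_sf = 3.5) {
  m <- matrix(1, 3, 3, dimnames = list(c("EB", "SF", "INH"),
                                       c("EB", "SF", "INH")))
  m["EB", "EB"] <- 2.5
  m["INH", "EB"] <- inh_to_eb
  m["INH", "SF"] <- inh_to_sf
  m
}

.px_table <- function() {
  px <- matrix(0, 3, 3, dimnames = list(c("EB", "SF", "INH"),
                                        c("EB", "SF", "INH")))
  px["EB", "SF"] <- 1
  px["SF", "EB"] <- 0.3
  px["SF", "SF"] <- 0.3
  px
}

# Random wiring: excitatory neurons connect to any other neuron with
# probability p_e; interneurons connect with probability p_i to neurons
# within `inh_radius` ring positions (the default radius spans the whole
# network).  No self-connections.
.wire <- function(role, p_e = 0.1, p_i = 0.5, inh_radius = Inf) {
  n <- length(role)
  pre <- rep(seq_len(n), each = n)
  post <- rep(seq_len(n), times = n)
  keep <- pre != post
  pre <- pre[keep]; post <- post[keep]
  p <- ifelse(role[pre] == "E", p_e, p_i)
  if (is.finite(inh_radius)) {
    d <- abs(pre - post)
    ringd <- pmin(d, n - d)
    p[role[pre] == "I" & ringd > inh_radius] <- 0
  }
  sel <- runif(length(pre)) < p
  data.frame(pre = pre[sel], post = post[sel])
}

.finish_network <- function(neurons, adj, kind, seed, scale,
                            mult, bias_edges = NULL, bias = 1) {
  pre_cl <- .group_class(neurons$group[adj$pre])
  post_cl <- .group_class(neurons$group[adj$post])
  px <- .px_table()
  edges <- data.frame(
    pre = adj$pre, post = adj$post,
    type = ifelse(neurons$role[adj$pre] == "E", "E", "I"),
    M = mult[cbind(pre_cl, post_cl)],
    w0 = 1,
    px = ifelse(neurons$role[adj$pre] == "E" & neurons$role[adj$post] == "E",
                px[cbind(pre_cl, post_cl)], 0))
  # backbone-internal plasticity is off regardless of table entries
  edges$px[pre_cl == "EB" & post_cl == "EB"] <- 0
  if (!is.null(bias_edges)) edges$w0[bias_edges(edges)] <- bias
  structure(list(neurons = neurons, edges = edges, kind = kind,
                 seed = seed, scale = scale),
            class = "engram_network")
}

#' Build the single-memory network
#'
#' 40 engram-backbone (EB) neurons with fixed, strengthened internal
#' connections (multiplier 2.5), 80 sparsely firing (SF) excitatory neurons
#' with plastic excitatory inputs, and 20 interneurons that inhibit the SF
#' population more strongly (multiplier 3.5) than the backbone (0.5).
#' Excitatory wiring is random at 10% density; interneurons contact 50% of
#' neurons within their connectivity radius (the whole network by default).
#' Excitatory cells receive `Idrive = 0.5` uA/cm2, interneurons -0.1.
#'
#' @param seed RNG seed controlling the wiring (and nothing else).
#' @param scale positive integer multiplying all population sizes (3
#'   reproduces the tripled-network control).
#' @param backbone_multiplier EB-internal synaptic multiplier; set to 1 to
#'   model the pre-learning baseline network without a strengthened engram.
#' @param m_eb_to_exc,m_eb_to_inh extra factors applied to EB output
#'   multipliers onto excitatory cells / interneurons (used by the
#'   functional-connectivity sweep).
#' @param inh_radius interneuron connectivity radius in ring positions.
#' @return An `engram_network`: list with `neurons` (id, group, role,
#'   idrive) and `edges` (pre, post, type, M, w0, px) tables.
#' @export
build_single_memory <- function(seed = 1, scale = 1,
                                backbone_multiplier = 2.5,
                                m_eb_to_exc = 1, m_eb_to_inh = 1,
                                inh_radius = Inf) {
  stopifnot(scale >= 1, scale == round(scale))
  n_eb <- 40 * scale; n_sf <- 80 * scale; n_inh <- 20 * scale
  neurons <- data.frame(
    id = seq_len(n_eb + n_sf + n_inh),
    group = c(rep("EB", n_eb), rep("SF", n_sf), rep("INH", n_inh)),
    role = c(rep("E", n_eb + n_sf), rep("I", n_inh)),
    idrive = c(rep(0.5, n_eb + n_sf), rep(-0.1, n_inh)))
  set.seed(seed)
  adj <- .wire(neurons$role, inh_radius = inh_radius)
  mult <- .multiplier_table()
  mult["EB", "EB"] <- backbone_multiplier
  mult["EB", c("EB", "SF")] <- mult["EB", c("EB", "SF")] * m_eb_to_exc
  mult["EB", "INH"] <- mult["EB", "INH"] * m_eb_to_inh
  .finish_network(neurons, adj, "single_memory", seed, scale, mult)
}

#' Build the equal-inhibition variant of the single-memory network
#'
#' Control network in which interneurons inhibit the backbone and SF
#' populations with the same multiplier (2.5) and the firing-rate contrast
#' is instead produced by intrinsic drive: `Idrive = 2` uA/cm2 for EB and
#' -0.5 for SF neurons.
#'
#' @inheritParams build_single_memory
#' @return An `engram_network`.
#' @export
build_equal_inhibition_variant <- function(seed = 1, scale = 1,
                                           inh_radius = Inf) {
  net <- build_single_memory(seed, scale, inh_radius = inh_radius)
  net$neurons$idrive[net$neurons$group == "EB"] <- 2
  net$neurons$idrive[net$neurons$group == "SF"] <- -0.5
  cl_pre <- .group_class(net$neurons$group[net$edges$pre])
  cl_post <- .group_class(net$neurons$group[net$edges$post])
  net$edges$M[cl_pre == "INH" & cl_post %in% c("EB", "SF")] <- 2.5
  net$kind <- "equal_inhibition"
  net
}

#' Assign SF quartiles from backbone in-degrees
#'
#' Splits the SF population into four equal groups by the number of
#' connections received from the two backbones: `SF_blue` (strong from
#' EB1, weak from EB2), `SF_green` (strong from EB2), `SF_pink` (weak from
#' both), `SF_violet` (strong from both).  SF neurons are ranked by the
#' in-degree difference d1 - d2 (top quarter blue, bottom quarter green);
#' the remaining half is ranked by d1 + d2 (top half violet, bottom half
#' pink).  Ties break by position.
#'
#' @param indeg matrix or data frame with one row per SF neuron and two
#'   columns: in-degree from EB1 and from EB2.
#' @return Character vector of group labels, one per SF neuron.
#' @export
#' @examples
#' assign_sf_quartiles(rbind(c(5, 1), c(1, 5), c(1, 1), c(5, 5)))
assign_sf_quartiles <- function(indeg) {
  indeg <- as.matrix(indeg)
  n <- nrow(indeg)
  if (n %% 4 != 0)
    stop("SF population size (", n, ") must be divisible by 4")
  q <- n / 4
  d1 <- indeg[, 1]; d2 <- indeg[, 2]
  lab <- rep(NA_character_, n)
  ord_diff <- order(d1 - d2, seq_len(n), decreasing = TRUE)
  lab[ord_diff[seq_len(q)]] <- "SF_blue"
  lab[ord_diff[seq(n - q + 1, n)]] <- "SF_green"
  mid <- which(is.na(lab))
  ord_sum <- mid[order(d1[mid] + d2[mid], mid, decreasing = TRUE)]
  lab[ord_sum[seq_len(q)]] <- "SF_violet"
  lab[ord_sum[seq(q + 1, 2 * q)]] <- "SF_pink"
  lab
}

#' Build the two-memory network
#'
#' Adds a second 40-neuron backbone (EB2) to the single-memory layout and
#' removes every direct EB1-EB2 connection to prevent runaway excitation.
#' SF neurons are divided into quartiles by their in-degree from the two
#' backbones (see [assign_sf_quartiles()]).  The pink and violet quartiles
#' receive a hyperpolarizing drive so they fire only sparsely and are not
#' recruited; blue and green quartiles have their inputs from their
#' preferred backbone initially strengthened by `bias`.
#'
#' @inheritParams build_single_memory
#' @param bias initial weight on EB1-to-blue and EB2-to-green edges
#'   (default 1.2, i.e. 20% strengthening; 1 removes the bias).
#' @param suppress_drive `Idrive` for the pink and violet SF quartiles,
#'   uA/cm2.
#' @return An `engram_network` with groups EB1, EB2, SF_blue, SF_green,
#'   SF_pink, SF_violet, INH.
#' @export
build_two_memory <- function(seed = 1, scale = 1, bias = 1.2,
                             suppress_drive = -6, inh_radius = Inf) {
  stopifnot(scale >= 1, scale == round(scale), bias >= 1)
  n_eb <- 40 * scale; n_sf <- 80 * scale; n_inh <- 20 * scale
  group <- c(rep("EB1", n_eb), rep("EB2", n_eb), rep("SF", n_sf),
             rep("INH", n_inh))
  role <- ifelse(group == "INH", "I", "E")
  neurons <- data.frame(id = seq_along(group), group = group, role = role,
                        idrive = ifelse(role == "I", -0.1, 0.5))
  set.seed(seed)
  adj <- .wire(role, inh_radius = inh_radius)
  # no backbone-to-backbone cross talk
  g <- neurons$group
  cross <- (g[adj$pre] == "EB1" & g[adj$post] == "EB2") |
           (g[adj$pre] == "EB2" & g[adj$post] == "EB1")
  adj <- adj[!cross, , drop = FALSE]

  sf_ids <- which(g == "SF")
  d1 <- vapply(sf_ids, function(i)
    sum(adj$post == i & g[adj$pre] == "EB1"), integer(1))
  d2 <- vapply(sf_ids, function(i)
    sum(adj$post == i & g[adj$pre] == "EB2"), integer(1))
  neurons$group[sf_ids] <- assign_sf_quartiles(cbind(d1, d2))
  suppressed <- neurons$group %in% c("SF_pink", "SF_violet")
  neurons$idrive[suppressed] <- suppress_drive

  bias_edges <- function(edges) {
    gg <- neurons$group
    (gg[edges$pre] == "EB1" & gg[edges$post] == "SF_blue") |
    (gg[edges$pre] == "EB2" & gg[edges$post] == "SF_green")
  }
  .finish_network(neurons, adj, "two_memory", seed, scale,
                  .multiplier_table(), bias_edges, bias)
}

#' @export
print.engram_network <- function(x, ...) {
  sizes <- table(x$neurons$group)
  cat("engram network (", x$kind, "), seed ", x$seed, "\n", sep = "")
  cat("  neurons:", paste(names(sizes), sizes, sep = "=", collapse = ", "),
      "\n")
  cat("  edges:", nrow(x$edges),
      sprintf("(%d plastic)", sum(x$edges$px > 0)), "\n")
  invisible(x)
}
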