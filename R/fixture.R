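#' Deterministic ciliomotor connectome fixture
#'
#' A synthetic stand-in for the reconstructed whole-body ciliomotor
#' connectome, built entirely in code. It reproduces the published cell
#' census and the published synapse budget of the main ciliomotor (MC)
#' neuron, and wires the remaining neuron classes with synthetic weights
#' that carry the circuit's left/right community structure:
#'
#' \itemize{
#'   \item 80 multiciliated cells: 23 prototroch, 8 akrotroch, 6 nuchal,
#'     1 crescent, 8 metatroch, and 8 + 14 + 12 paratroch cells
#'     (segments I-III).
#'   \item The MC neuron is presynaptic to every prototroch cell with
#'     3-25 synapses per cell, 335 synapses onto the prototroch in total,
#'     and 341 outgoing synapses overall (the remaining 6 are placed on
#'     two metatroch cells; their placement is synthetic, the paper names
#'     no targets for them).
#'   \item Loop neurons innervate the ipsilateral paratroch, akrotroch
#'     and nuchal cells, the crescent cell (their only input), and lateral
#'     prototroch cells; Ser-tr1 and MN-ant neurons innervate contralateral
#'     trunk bands including the metatroch; Ser-h1 and the three cMN
#'     neurons innervate the prototroch and interconnect with MC. All
#'     non-MC weights are synthetic (the source text prints none): they
#'     plant the three-community organisation — a prototroch/head module
#'     around MC and two left/right trunk modules — that module detection
#'     should recover.
#' }
#'
#' @return a `ciliomotor_network`
#' @export
#' @examples
#' net <- make_paper_fixture()
#' length(select_ciliomotor(net))
make_paper_fixture <- function() {
  side_split <- function(n, n_left) {
    c(rep("left", n_left), rep("right", n - n_left))
  }
  ciliated <- rbind(
    data.frame(id = sprintf("proto_%d", 1:23), group = "prototroch",
               side = c(rep("left", 11), rep("right", 11), "unpaired")),
    data.frame(id = sprintf("akro_%d", 1:8), group = "akrotroch",
               side = side_split(8, 4)),
    data.frame(id = sprintf("nuchal_%d", 1:6), group = "nuchal",
               side = side_split(6, 3)),
    data.frame(id = "crescent_1", group = "crescent", side = "unpaired"),
    data.frame(id = sprintf("meta_%d", 1:8), group = "metatroch",
               side = side_split(8, 4)),
    data.frame(id = sprintf("para_I_%d", 1:8), group = "paratroch_I",
               side = side_split(8, 4)),
    data.frame(id = sprintf("para_II_%d", 1:14), group = "paratroch_II",
               side = side_split(14, 7)),
    data.frame(id = sprintf("para_III_%d", 1:12), group = "paratroch_III",
               side = side_split(12, 6)))
  ciliated$cell_class <- "multiciliated"
  ciliated$transmitter <- "unknown"
  neurons <- data.frame(
    id = c("MC", "Loop_l", "Loop_r", "MN_ant_l", "MN_ant_r",
           "Ser_h1_l", "Ser_h1_r", "Ser_tr1_l", "Ser_tr1_r",
           "cMN_vl", "cMN_d", "cMN_ATO"),
    cell_class = "neuron",
    group = c("MC", "Loop", "Loop", "MN_ant", "MN_ant",
              "Ser_h1", "Ser_h1", "Ser_tr1", "Ser_tr1",
              "cMN", "cMN", "cMN"),
    side = c("unpaired", "left", "right", "left", "right",
             "left", "right", "left", "right",
             "left", "unpaired", "unpaired"),
    transmitter = c("cholinergic", "cholinergic", "cholinergic",
                    "cholinergic", "cholinergic",
                    "serotonergic", "serotonergic",
                    "serotonergic", "serotonergic",
                    rep("catecholaminergic_peptidergic", 3)))
  ann <- rbind(ciliated[names(neurons)], neurons)

  e <- function(pre, post, w) data.frame(pre = pre, post = post, weight = w)
  left_of <- function(g) ciliated$id[ciliated$group %in% g &
                                     ciliated$side == "left"]
  right_of <- function(g) ciliated$id[ciliated$group %in% g &
                                      ciliated$side == "right"]
  trunk <- c("paratroch_I", "paratroch_II", "paratroch_III")

  # MC -> prototroch: 23 weights in [3, 25] summing to 335 (published
  # range, total and target count); the per-cell assignment is a fixed,
  # documented sequence -- any sequence meeting those constraints would do.
  mc_w <- c(3, 25, rep(15, 13), rep(14, 8))
  stopifnot(sum(mc_w) == 335, all(mc_w >= 3), all(mc_w <= 25))
  edges <- rbind(
    e("MC", sprintf("proto_%d", 1:23), mc_w),
    e("MC", c("meta_1", "meta_5"), 3),              # synthetic placement
    # Loop neurons: ipsilateral trunk bands + head cilia + crescent
    e("Loop_l", left_of(trunk), 5),
    e("Loop_l", left_of("akrotroch"), 5),
    e("Loop_l", left_of("nuchal"), 5),
    e("Loop_l", "crescent_1", 5),
    e("Loop_l", sprintf("proto_%d", 2:6), 2),       # lateral prototroch
    e("Loop_r", right_of(trunk), 5),
    e("Loop_r", right_of("akrotroch"), 5),
    e("Loop_r", right_of("nuchal"), 5),
    e("Loop_r", "crescent_1", 5),
    e("Loop_r", sprintf("proto_%d", 13:17), 2),
    # Ser-tr1: contralateral paratroch + metatroch, ipsilateral prototroch
    e("Ser_tr1_l", right_of(trunk), 4),
    e("Ser_tr1_l", right_of("metatroch"), 4),
    e("Ser_tr1_l", sprintf("proto_%d", 7:9), 2),
    e("Ser_tr1_r", left_of(trunk), 4),
    e("Ser_tr1_r", left_of("metatroch"), 4),
    e("Ser_tr1_r", sprintf("proto_%d", 18:20), 2),
    # MN-ant: contralateral prototroch, metatroch, paratroch I
    e("MN_ant_l", sprintf("proto_%d", 18:20), 2),
    e("MN_ant_l", right_of("metatroch"), 3),
    e("MN_ant_l", right_of("paratroch_I"), 2),
    e("MN_ant_r", sprintf("proto_%d", 8:10), 2),
    e("MN_ant_r", left_of("metatroch"), 3),
    e("MN_ant_r", left_of("paratroch_I"), 2),
    # Ser-h1: synapses spread along the whole prototroch ring nerve
    e("Ser_h1_l", sprintf("proto_%d", seq(2, 22, by = 2)), 2),
    e("Ser_h1_r", sprintf("proto_%d", seq(1, 23, by = 2)), 2),
    # cMN neurons: interleaved prototroch targets + neuron-neuron links
    e("cMN_vl", sprintf("proto_%d", seq(1, 23, by = 3)), 2),
    e("cMN_d", sprintf("proto_%d", seq(2, 23, by = 3)), 2),
    e("cMN_ATO", sprintf("proto_%d", seq(3, 23, by = 3)), 2),
    e(c("cMN_vl", "cMN_d", "cMN_ATO"), "MC", 5),
    e("cMN_vl", c("Loop_l", "Loop_r"), 2),
    e("cMN_d", "Ser_h1_l", 2),
    e("Ser_h1_l", "cMN_d", 2))
  load_edge_table(edges, ann)
}
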