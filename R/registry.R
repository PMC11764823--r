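#' Food-item registry
#'
#' The thirteen food items served across the two study menus (A and B), with
#' their meal slot, menu membership, per-serving energy, the number of raw
#' 5 Hz accelerometer records collected for each item in the original study,
#' and whether the item is typically eaten moving both hands actively.
#' Yogurt appears on both menus; every other item belongs to exactly one.
#'
#' @return A data frame with one row per food item and columns
#'   \code{food_id} (zero-padded character, \code{"01"}--\code{"13"}),
#'   \code{food_item}, \code{meal}, \code{menu} (\code{"A"}, \code{"B"} or
#'   \code{"A/B"}), \code{kcal_per_serving}, \code{raw_records} and
#'   \code{two_handed}.
#' @examples
#' sum(food_registry()$raw_records)
#' @export
food_registry <- function() {
  data.frame(
    food_id = sprintf("%02d", 1:13),
    food_item = c("Rusks and Jelly", "Yogurt", "Croissant", "Risotto",
                  "Taglierini", "Mozzarella", "Meatballs", "Biscuits",
                  "Sandwich", "Legume soup", "Artichoke and Chicken",
                  "Parmigiana", "Stracchino"),
    meal = c("Breakfast", "Breakfast", "Breakfast", "Lunch", "Lunch", "Lunch",
             "Lunch", "Snack", "Snack", "Dinner", "Dinner", "Dinner",
             "Dinner"),
    menu = c("A", "A/B", "B", "A", "B", "A", "B", "A", "B", "A", "A", "B",
             "B"),
    kcal_per_serving = c(114, 186, 99, 471, 546, 242, 135, 278, 195, 135,
                         199, 309, 269),
    raw_records = c(15830, 40114, 9224, 32422, 30458, 15450, 11240, 22090,
                    17652, 19034, 17984, 31436, 15326),
    two_handed = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, FALSE,
                   TRUE, FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )
}

#' Names of the seven kinetic variables
#'
#' The per-sample channels the pipeline derives from raw triaxial
#' acceleration: the three axes, pitch, roll, power (acceleration magnitude)
#' and total energy (power purged of gravity). Window slope features follow
#' this order, per wrist.
#'
#' @return Character vector of length 7.
#' @export
kinetic_variables <- function() {
  c("x_mG", "y_mG", "z_mG", "pitch_rad", "roll_rad", "power_mG",
    "total_energy_mG")
}

#' Foods on a given menu
#'
#' @param menu \code{"A"} or \code{"B"}.
#' @return Character vector of the seven food ids served on that menu, in
#'   meal order.
#' @export
menu_foods <- function(menu = c("A", "B")) {
  menu <- match.arg(menu)
  reg <- food_registry()
  reg$food_id[reg$menu %in% c(menu, "A/B")]
}

# Standard gravity in the watch's units. All magnitudes are in milli-G.
.G_MG <- 1000
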