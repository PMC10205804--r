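name: specific_satiety
groups:
  prefed: 8
start_clock: 480.0
series: no
steps:
  prefed:
  - op: wait
    minutes: 150.0
  - op: add_food
    type: mealworm
    amount: 30
  - op: wait
    minutes: 10.0
  - op: measure
    what: count_food_items
    type: mealworm
    name: prefeed_remaining_10
  - op: wait
    minutes: 10.0
  - op: measure
    what: count_food_items
    type: mealworm
    name: prefeed_remaining_20
  - op: wait
    minutes: 10.0
  - op: measure
    what: count_food_items
    type: mealworm
    name: prefeed_remaining
  - op: remove_food
    type: mealworm
  - op: add_food
    type: mealworm
    amount: 15
  - op: add_food
    type: peanut
    amount: 15
  - op: wait
    minutes: 5.0
  - op: measure
    what: count_food_items
    type: mealworm
    name: test_remaining_prefed_5
  - op: measure
    what: count_food_items
    type: peanut
    name: test_remaining_other_5
  - op: wait
    minutes: 10.0
  - op: measure
    what: count_food_items
    type: mealworm
    name: test_remaining_prefed_15
  - op: measure
    what: count_food_items
    type: peanut
    name: test_remaining_other_15
tests:
- name: p_satiety
  type: t_paired
  group: prefed
  q1: test_remaining_prefed_15
  q2: test_remaining_other_15

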