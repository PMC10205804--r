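name: dekort07_exp4
groups:
  control: 4
  pilfered: 4
start_clock: 480.0
series: no
steps:
  control:
  - op: wait
    minutes: 60.0
  - op: add_tray
    tray: A
    appearance: 1
    position: 1
    open: yes
  - op: add_tray
    tray: B
    appearance: 2
    position: 2
    open: no
  - op: add_food
    type: mealworm
    amount: 12
  - op: wait
    minutes: 15.0
  - op: measure
    what: count_cached_items
    tray: A
    name: cache_A_trial1
  - op: remove_food
    type: mealworm
  - op: cover
    tray: A
  - op: wait
    minutes: 1365.0
  - op: uncover
    tray: A
  - op: uncover
    tray: B
  - op: wait
    minutes: 20.0
  - op: cover
    tray: A
  - op: cover
    tray: B
  - op: wait
    minutes: 50.0
  - op: pilfer
    tray: A
  - op: pilfer
    tray: B
  - op: uncover
    tray: A
  - op: add_food
    type: mealworm
    amount: 12
  - op: wait
    minutes: 15.0
  - op: measure
    what: count_cached_items
    tray: A
    name: cache_A_trial2
  - op: remove_food
    type: mealworm
  - op: cover
    tray: A
  - op: wait
    minutes: 1365.0
  - op: uncover
    tray: A
  - op: uncover
    tray: B
  - op: wait
    minutes: 20.0
  - op: cover
    tray: A
  - op: cover
    tray: B
  - op: wait
    minutes: 50.0
  - op: pilfer
    tray: A
  - op: pilfer
    tray: B
  - op: uncover
    tray: A
  - op: uncover
    tray: B
  - op: add_food
    type: mealworm
    amount: 12
  - op: wait
    minutes: 15.0
  - op: measure
    what: count_cached_items
    tray: A
    name: cache_A_final
  - op: measure
    what: count_cached_items
    tray: B
    name: cache_B_final
  pilfered:
  - op: wait
    minutes: 60.0
  - op: add_tray
    tray: A
    appearance: 1
    position: 1
    open: yes
  - op: add_tray
    tray: B
    appearance: 2
    position: 2
    open: no
  - op: add_food
    type: mealworm
    amount: 12
  - op: wait
    minutes: 15.0
  - op: measure
    what: count_cached_items
    tray: A
    name: cache_A_trial1
  - op: remove_food
    type: mealworm
  - op: cover
    tray: A
  - op: pilfer
    tray: A
  - op: wait
    minutes: 1365.0
  - op: uncover
    tray: A
  - op: uncover
    tray: B
  - op: wait
    minutes: 20.0
  - op: cover
    tray: A
  - op: cover
    tray: B
  - op: wait
    minutes: 50.0
  - op: pilfer
    tray: A
  - op: pilfer
    tray: B
  - op: uncover
    tray: A
  - op: add_food
    type: mealworm
    amount: 12
  - op: wait
    minutes: 15.0
  - op: measure
    what: count_cached_items
    tray: A
    name: cache_A_trial2
  - op: remove_food
    type: mealworm
  - op: cover
    tray: A
  - op: pilfer
    tray: A
  - op: wait
    minutes: 1365.0
  - op: uncover
    tray: A
  - op: uncover
    tray: B
  - op: wait
    minutes: 20.0
  - op: cover
    tray: A
  - op: cover
    tray: B
  - op: wait
    minutes: 50.0
  - op: pilfer
    tray: A
  - op: pilfer
    tray: B
  - op: uncover
    tray: A
  - op: uncover
    tray: B
  - op: add_food
    type: mealworm
    amount: 12
  - op: wait
    minutes: 15.0
  - op: measure
    what: count_cached_items
    tray: A
    name: cache_A_final
  - op: measure
    what: count_cached_items
    tray: B
    name: cache_B_final
tests:
- name: p_cache_A
  type: t_ind
  quantity: cache_A_final
  groups:
  - control
  - pilfered

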