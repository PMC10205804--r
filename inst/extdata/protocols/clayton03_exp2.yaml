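name: clayton03_exp2
groups:
  manipulated: 8
start_clock: 480.0
series: no
steps:
  manipulated:
  - op: wait
    minutes: 60.0
  - op: add_tray
    tray: P1
    appearance: 1
    position: 1
    open: yes
  - op: add_food
    type: peanut
    amount: 5
  - op: wait
    minutes: 15.0
  - op: measure
    what: count_cached_items
    tray: P1
    name: cache_peanut_day1
  - op: remove_food
    type: peanut
  - op: cover
    tray: P1
  - op: wait
    minutes: 5.0
  - op: add_tray
    tray: C1
    appearance: 2
    position: 2
    open: yes
  - op: add_food
    type: cricket
    amount: 5
  - op: wait
    minutes: 15.0
  - op: measure
    what: count_cached_items
    tray: C1
    name: cache_cricket_day1
  - op: remove_food
    type: cricket
  - op: cover
    tray: C1
  - op: wait
    minutes: 1345.0
  - op: wait
    minutes: 60.0
  - op: add_tray
    tray: P2
    appearance: 3
    position: 3
    open: yes
  - op: add_food
    type: peanut
    amount: 5
  - op: wait
    minutes: 15.0
  - op: measure
    what: count_cached_items
    tray: P2
    name: cache_peanut_day2
  - op: remove_food
    type: peanut
  - op: cover
    tray: P2
  - op: wait
    minutes: 5.0
  - op: add_tray
    tray: C2
    appearance: 4
    position: 4
    open: yes
  - op: add_food
    type: cricket
    amount: 5
  - op: wait
    minutes: 15.0
  - op: measure
    what: count_cached_items
    tray: C2
    name: cache_cricket_day2
  - op: remove_food
    type: cricket
  - op: cover
    tray: C2
  - op: wait
    minutes: 1345.0
  - op: wait
    minutes: 60.0
  - op: add_tray
    tray: P3
    appearance: 5
    position: 5
    open: yes
  - op: add_food
    type: peanut
    amount: 5
  - op: wait
    minutes: 15.0
  - op: measure
    what: count_cached_items
    tray: P3
    name: cache_peanut_day3
  - op: remove_food
    type: peanut
  - op: cover
    tray: P3
  - op: wait
    minutes: 5.0
  - op: add_tray
    tray: C3
    appearance: 6
    position: 6
    open: yes
  - op: add_food
    type: cricket
    amount: 5
  - op: wait
    minutes: 15.0
  - op: measure
    what: count_cached_items
    tray: C3
    name: cache_cricket_day3
  - op: remove_food
    type: cricket
  - op: cover
    tray: C3
  - op: wait
    minutes: 1345.0
  - op: wait
    minutes: 60.0
  - op: degrade
    tray: C1
  - op: uncover
    tray: P1
  - op: uncover
    tray: C1
  - op: wait
    minutes: 10.0
  - op: cover
    tray: P1
  - op: cover
    tray: C1
  - op: remove_food
    type: peanut
  - op: remove_food
    type: cricket
  - op: wait
    minutes: 1370.0
  - op: wait
    minutes: 60.0
  - op: degrade
    tray: C2
  - op: uncover
    tray: P2
  - op: uncover
    tray: C2
  - op: wait
    minutes: 10.0
  - op: cover
    tray: P2
  - op: cover
    tray: C2
  - op: remove_food
    type: peanut
  - op: remove_food
    type: cricket
  - op: wait
    minutes: 1370.0
  - op: wait
    minutes: 60.0
  - op: pilfer
    tray: P3
  - op: pilfer
    tray: C3
  - op: add_observer
    id: obs
    appearances:
    - 5
    - 6
  - op: uncover
    tray: P3
  - op: uncover
    tray: C3
  - op: wait
    minutes: 5.0
  - op: measure
    what: count_inspections
    observer: obs
    appearance: 5
    name: inspect_peanut_side
  - op: measure
    what: count_inspections
    observer: obs
    appearance: 6
    name: inspect_cricket_side
tests:
- name: p_side
  type: t_paired
  group: manipulated
  q1: inspect_peanut_side
  q2: inspect_cricket_side

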