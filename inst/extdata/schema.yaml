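dimensions:
  - id: resource
    name: Resource acquisition capability
  - id: functional
    name: Functional performance capacity
  - id: performance
    name: Performance development level
  - id: learning
    name: Learning and development ability
  - id: internet
    name: Internet application
indicators:
  - id: I_1
    name: Per capita GDP
    unit: ten thousand yuan
    dimension: resource
    nature: positive
  - id: I_2
    name: Per capita fiscal revenue
    unit: ten thousand yuan
    dimension: resource
    nature: positive
  - id: I_3
    name: Regional informatization level
    unit: index
    dimension: resource
    nature: positive
  - id: I_4
    name: Number of administrative acceptances
    unit: piece
    dimension: functional
    nature: positive
  - id: I_5
    name: Approved re-registration applications of domestic drugs
    unit: piece
    dimension: functional
    nature: positive
  - id: I_6
    name: Relative change in registered licensed pharmacists
    unit: index
    dimension: functional
    nature: positive
  - id: I_7
    name: Qualified rate of drug sampling
    unit: "%"
    dimension: performance
    nature: positive
  - id: I_8
    name: Production department qualified rate
    unit: "%"
    dimension: performance
    nature: positive
  - id: I_9
    name: Operating department qualified rate
    unit: "%"
    dimension: performance
    nature: positive
  - id: I_10
    name: Scientific research input
    unit: ten thousand yuan
    dimension: learning
    nature: positive
  - id: I_11
    name: Training expense
    unit: ten thousand yuan
    dimension: learning
    nature: positive
  - id: I_12
    name: Total site visits
    unit: count
    dimension: internet
    nature: positive
  - id: I_13
    name: Released information items
    unit: count
    dimension: internet
    nature: positive
  - id: I_14
    name: Share of government affairs fully handleable online
    unit: "%"
    dimension: internet
    nature: positive
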