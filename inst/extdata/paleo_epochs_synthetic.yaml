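# Synthetic six-epoch landmass connectivity configuration.
# The epoch bounds follow the six tectonic intervals used for
# time-stratified dispersal matrices (0-3, 3-14, 14-50, 50-66, 66-94,
# 94-133.27 Ma). The Quaternary epoch encodes the worked four-area
# example exactly; the older epochs are illustrative connectivities for
# exercising the stratified machinery, not a paleogeographic
# reconstruction.
areas:
  - name: NorthAmerica
  - name: Eurasia
  - name: IndoPacific
    inhabitable: false
  - name: Australia
epochs:
  - start_Ma: 0
    end_Ma: 3
    pairs:
      - {from: NorthAmerica, to: Eurasia, class: atlantic-class-ocean}
      - {from: Eurasia, to: IndoPacific, class: close-islands}
      - {from: IndoPacific, to: Australia, class: close-islands}
      - {from: NorthAmerica, to: Australia, class: pacific-class-ocean}
  - start_Ma: 3
    end_Ma: 14
    pairs:
      - {from: NorthAmerica, to: Eurasia, class: atlantic-class-ocean}
      - {from: Eurasia, to: IndoPacific, class: close-islands}
      - {from: IndoPacific, to: Australia, class: close-islands}
      - {from: NorthAmerica, to: Australia, class: pacific-class-ocean}
  - start_Ma: 14
    end_Ma: 50
    pairs:
      - {from: NorthAmerica, to: Eurasia, class: atlantic-class-ocean}
      - {from: Eurasia, to: IndoPacific, class: close-islands}
      - {from: IndoPacific, to: Australia, class: pacific-class-ocean}
      - {from: NorthAmerica, to: Australia, class: pacific-class-ocean}
  - start_Ma: 50
    end_Ma: 66
    pairs:
      - {from: NorthAmerica, to: Eurasia, class: connected}
      - {from: Eurasia, to: IndoPacific, class: atlantic-class-ocean}
      - {from: IndoPacific, to: Australia, class: pacific-class-ocean}
  - start_Ma: 66
    end_Ma: 94
    pairs:
      - {from: NorthAmerica, to: Eurasia, class: connected}
      - {from: Eurasia, to: IndoPacific, class: atlantic-class-ocean}
      - {from: IndoPacific, to: Australia, class: pacific-class-ocean}
  - start_Ma: 94
    end_Ma: 133.27
    pairs:
      - {from: NorthAmerica, to: Eurasia, class: connected}
      - {from: Eurasia, to: IndoPacific, class: atlantic-class-ocean}
      - {from: IndoPacific, to: Australia, class: pacific-class-ocean}
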