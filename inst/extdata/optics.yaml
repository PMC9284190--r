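leds:
- name: L385
  emission: spectra/led_L385_emission.csv
  excitation_filter: spectra/filter_L385_excitation.csv
- name: L470
  emission: spectra/led_L470_emission.csv
  excitation_filter: spectra/filter_L470_excitation.csv
- name: L567
  emission: spectra/led_L567_emission.csv
  excitation_filter: spectra/filter_L567_excitation.csv
- name: L627
  emission: spectra/led_L627_emission.csv
  excitation_filter: spectra/filter_L627_excitation.csv
- name: L720
  emission: spectra/led_L720_emission.csv
  excitation_filter: spectra/filter_L720_excitation.csv
fluorochromes:
- name: DAPI
  excitation: spectra/fluor_DAPI_excitation.csv
  emission: spectra/fluor_DAPI_emission.csv
  brightness: 1.0
- name: BV605
  excitation: spectra/fluor_BV605_excitation.csv
  emission: spectra/fluor_BV605_emission.csv
  brightness: 1.0
- name: AF488
  excitation: spectra/fluor_AF488_excitation.csv
  emission: spectra/fluor_AF488_emission.csv
  brightness: 1.0
- name: AF555
  excitation: spectra/fluor_AF555_excitation.csv
  emission: spectra/fluor_AF555_emission.csv
  brightness: 1.0
- name: AF647
  excitation: spectra/fluor_AF647_excitation.csv
  emission: spectra/fluor_AF647_emission.csv
  brightness: 1.2
- name: CF750
  excitation: spectra/fluor_CF750_excitation.csv
  emission: spectra/fluor_CF750_emission.csv
  brightness: 0.8
penta:
  transmission: spectra/penta_transmission.csv
  passbands:
  - - 414.0
    - 450.0
  - - 500.0
    - 530.0
  - - 579.0
    - 611.0
  - - 661.0
    - 701.0
  - - 779.0
    - 839.0
sensor:
  r: spectra/sensor_R.csv
  g: spectra/sensor_G.csv
  b: spectra/sensor_B.csv
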