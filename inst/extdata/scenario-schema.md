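# Scenario XML dialect

This dialect is a documented reconstruction: scenario scripts for smart-home
simulators are conventionally XML files listing events chronologically, but
no normative grammar exists, so the package fixes one and ships it here.
`read_scenario()` / `write_scenario()` round-trip it exactly.

```xml
<scenario duration="604800">
  <zones>
    <zone name="bathroom"/>
    <zone name="livingroom"/>
  </zones>
  <sensors>
    <sensor id="bathroom_door" kind="magnetic" attribute="Open/Close"
            value-type="boolean" zone="bathroom" device="door"/>
    <sensor id="glucometer" kind="medical" attribute="measurement"
            value-type="real" zone="livingroom" device="glucometer"
            range-min="10" range-max="600"/>
  </sensors>
  <persons>
    <person id="resident"/>
  </persons>
  <script>
    <command at="120" kind="set-device"      target="bathroom_door" value="true"/>
    <command at="300" kind="move-person"     target="resident"      value="bathroom"/>
    <command at="500" kind="set-zone-var"    target="bathroom#temperature" value="21.5"/>
    <command at="900" kind="medical-reading" target="glucometer"    value="101.5"/>
  </script>
</scenario>
```

Rules:

* `duration` (seconds) must cover the last command time; the scenario epoch
  is always second 0.
* `sensor/@kind` is one of `electromagnetic`, `proximity`, `capacitive`,
  `magnetic`, `presence`, `medical`; `value-type` (`boolean`, `real`,
  `text`) must be compatible with the kind (proximity sensors are real,
  medical sensors real or text, the rest boolean).
* `command/@kind` is one of `set-device`, `move-person`, `set-zone-var`,
  `medical-reading`. Targets must resolve against the declared sensors,
  persons, or zones (`set-zone-var` targets are `zone#variable`).
* Commands should be sorted by `at`; unsorted scripts are accepted with a
  warning and sorted stably.
* Clock-speed facilities of interactive simulators are irrelevant here:
  execution is event-driven batch, so a scenario always replays
  identically.
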